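# Fixture molecules with hand-assigned fragment counts, and alternative
# SMILES spellings of the same structures (atom-renumbered, frozen) for the
# spelling-invariance property.

fixtureCounts <- function(...) {
  p <- fragkin::FragmentProfile(c(...))
  fragkin::fragmentCounts(p)
}

fixtureMolecules <- list(
  benzene  = list(smiles = "c1ccccc1", counts = fixtureCounts(aromatic = 1)),
  ethanol  = list(smiles = "CCO", counts = fixtureCounts(hydroxyl = 1)),
  phenol   = list(smiles = "Oc1ccccc1",
                  counts = fixtureCounts(aromatic = 1, hydroxyl = 1)),
  naphthalene = list(smiles = "c1ccc2ccccc2c1",
                     counts = fixtureCounts(aromatic = 2)),
  aspirin  = list(smiles = "CC(=O)Oc1ccccc1C(=O)O",
                  counts = fixtureCounts(aromatic = 1, ester = 1,
                                         carboxylic_acid = 1)),
  hexane   = list(smiles = "CCCCCC", counts = fixtureCounts()),
  anisole  = list(smiles = "COc1ccccc1",
                  counts = fixtureCounts(aromatic = 1, ether = 1)),
  aniline  = list(smiles = "Nc1ccccc1",
                  counts = fixtureCounts(aromatic = 1, amine = 1)),
  acetone  = list(smiles = "CC(C)=O", counts = fixtureCounts(ketone = 1)),
  lidocaine = list(smiles = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
                   counts = fixtureCounts(aromatic = 1, amide = 1,
                                          amine = 1)),
  pcresol  = list(smiles = "Cc1ccc(O)cc1",
                  counts = fixtureCounts(aromatic = 1, hydroxyl = 1)),
  bromochloro = list(smiles = "Brc1ccc(Cl)cc1",
                     counts = fixtureCounts(aromatic = 1, bromine = 1,
                                            chlorine = 1))
)

# Frozen alternative spellings (atom renumberings) of fixture structures.
altSpellings <- list(
  benzene = c('c1ccccc1'),
  aspirin = c('C(Oc1c(C(O)=O)cccc1)(C)=O', 'CC(=O)Oc1c(C(O)=O)cccc1', 'CC(Oc1c(C(O)=O)cccc1)=O', 'O(C(=O)C)c1ccccc1C(=O)O', 'O(C(=O)C)c1ccccc1C(O)=O', 'O(c1c(C(=O)O)cccc1)C(=O)C', 'O=C(C)Oc1ccccc1C(=O)O', 'O=C(C)Oc1ccccc1C(O)=O', 'O=C(c1c(OC(=O)C)cccc1)O', 'c1(C(=O)O)ccccc1OC(C)=O', 'c1(OC(=O)C)ccccc1C(=O)O', 'c1c(C(=O)O)c(OC(C)=O)ccc1', 'c1c(OC(=O)C)c(C(=O)O)ccc1', 'c1c(OC(C)=O)c(C(O)=O)ccc1', 'c1cc(OC(=O)C)c(C(=O)O)cc1', 'c1cc(OC(C)=O)c(C(=O)O)cc1', 'c1ccc(C(=O)O)c(OC(C)=O)c1', 'c1cccc(C(=O)O)c1OC(C)=O', 'c1cccc(C(O)=O)c1OC(C)=O', 'c1cccc(OC(C)=O)c1C(=O)O'),
  pcresol = c('Cc1ccc(O)cc1', 'Oc1ccc(C)cc1', 'c1(C)ccc(O)cc1', 'c1(O)ccc(C)cc1', 'c1c(C)ccc(O)c1', 'c1c(O)ccc(C)c1', 'c1cc(C)ccc1O', 'c1cc(O)ccc1C'),
  lidocaine = c('C(C(=O)Nc1c(C)cccc1C)N(CC)CC', 'C(C(Nc1c(C)cccc1C)=O)N(CC)CC', 'C(C)N(CC(Nc1c(C)cccc1C)=O)CC', 'C(N(CC)CC(Nc1c(C)cccc1C)=O)C', 'C(N(CC)CC)C(=O)Nc1c(C)cccc1C', 'C(N(CC)CC)C(Nc1c(C)cccc1C)=O', 'C(Nc1c(C)cccc1C)(=O)CN(CC)CC', 'C(Nc1c(C)cccc1C)(CN(CC)CC)=O', 'CCN(CC(Nc1c(C)cccc1C)=O)CC', 'CCN(CC)CC(=O)Nc1c(C)cccc1C', 'N(c1c(C)cccc1C)C(=O)CN(CC)CC', 'N(c1c(C)cccc1C)C(CN(CC)CC)=O', 'O=C(Nc1c(C)cccc1C)CN(CC)CC', 'c1(C)cccc(C)c1NC(=O)CN(CC)CC', 'c1(C)cccc(C)c1NC(CN(CC)CC)=O', 'c1(NC(=O)CN(CC)CC)c(C)cccc1C', 'c1c(C)c(NC(=O)CN(CC)CC)c(C)cc1', 'c1cc(C)c(NC(=O)CN(CC)CC)c(C)c1', 'c1cc(C)c(NC(CN(CC)CC)=O)c(C)c1', 'c1ccc(C)c(NC(=O)CN(CC)CC)c1C'),
  ibuprofen = c('C(C(=O)O)(c1ccc(CC(C)C)cc1)C', 'C(C(C)C)c1ccc(C(C(=O)O)C)cc1', 'C(C(C)c1ccc(CC(C)C)cc1)(O)=O', 'C(C(c1ccc(CC(C)C)cc1)C)(O)=O', 'C(Cc1ccc(C(C)C(O)=O)cc1)(C)C', 'C(O)(=O)C(C)c1ccc(CC(C)C)cc1', 'C(c1ccc(C(C(O)=O)C)cc1)C(C)C', 'C(c1ccc(C(C)C(O)=O)cc1)C(C)C', 'C(c1ccc(CC(C)C)cc1)(C)C(=O)O', 'C(c1ccc(CC(C)C)cc1)(C)C(O)=O', 'CC(C(O)=O)c1ccc(CC(C)C)cc1', 'OC(=O)C(C)c1ccc(CC(C)C)cc1', 'OC(=O)C(c1ccc(CC(C)C)cc1)C', 'OC(C(c1ccc(CC(C)C)cc1)C)=O', 'c1(C(C(=O)O)C)ccc(CC(C)C)cc1', 'c1(C(C)C(=O)O)ccc(CC(C)C)cc1', 'c1(CC(C)C)ccc(C(C)C(=O)O)cc1', 'c1cc(C(C)C(O)=O)ccc1CC(C)C', 'c1cc(CC(C)C)ccc1C(C(=O)O)C', 'c1cc(CC(C)C)ccc1C(C)C(=O)O')
)

# Build a toy permeability CSV; fields default to the bundled fixture layout.
writeToyCsv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

toyRecord <- function(compound, logkp, source = "abdomen",
                      layer = "epidermis", donor = "diluted",
                      temperature_c = 33, ph = 7.2, smiles = NA,
                      reference = "toy") {
  data.frame(compound = compound, smiles = smiles, logkp = logkp,
             source = source, layer = layer, donor = donor,
             temperature_c = temperature_c, ph = ph, reference = reference,
             stringsAsFactors = FALSE)
}
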