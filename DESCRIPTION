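Package: glycotandem
Title: Glycan-Database-Independent Identification and Quantification of
    Intact N-Glycopeptides from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies intact N-glycopeptides from stepped-collision-energy
    HCD LC-MS/MS runs without committing to a glycan database at the peptide
    identification stage. Candidate peptide-backbone masses are derived from
    the conserved pentasaccharide-core Y-ion ladder, glycan-derived peaks are
    stripped and the precursor rewritten to produce in-silico deglycosylated
    spectra for a proteomic search; unidentified glycopeptide spectra are then
    recovered by matching each backbone's conserved fragmentation pattern
    within a retention-time window, with decoy-spectrum e-values controlling
    the false discovery rate. Glycan compositions are assigned by B/Y-ion
    scoring against a composition database or, for modified glycans, by
    monosaccharide stepping along the Y-ion series; site-specific glycoforms
    are quantified from MS1 isotope-envelope elution profiles. A synthetic-run
    generator with ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    mzR,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'masscalc.R'
    'AllClasses.R'
    'spectra-io.R'
    'oxonium.R'
    'deglyco.R'
    'peptides.R'
    'expansion.R'
    'glycan-db.R'
    'glycan-annotate.R'
    'glycan-profile.R'
    'quant.R'
    'simulate.R'
    'pipeline.R'
    'glycotandem-package.R'
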