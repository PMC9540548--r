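Package: bhcontext
Title: Joint Chemical Context Prediction for Buchwald-Hartwig Coupling Reactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the chemical context -- the joint set of (pre-)catalyst, ligand,
    base, solvent and reagents -- for Buchwald-Hartwig C-N coupling reactions.
    Implements the full pipeline from raw electronic-lab-notebook-style reaction
    records to trained single-label and multi-label feed-forward classifiers:
    role assignment and canonical context construction, yield and popularity
    filtering, difference reaction fingerprints (circular radius-3 plus
    linear-path hashed bits), network training with yield-weighted losses,
    multi-label ranking metrics (LRAP, samples Jaccard, rank curves,
    per-context sensitivity/specificity, confusion likelihoods, partial
    agreement), dataset imbalance and cardinality statistics, per-year context
    usage and year-ranged retraining experiments, and a synthetic ELN-like data
    generator with planted, learnable context rules and temporal context drift.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
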