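Package: domctx
Title: Directional Domain-Context Scoring and Optimal Selection for
    Protein Domain Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processes permissive profile-HMM domain searches (HMMER3
    'hmmscan --domtblout' tables) using directional domain co-occurrence.
    Candidate domains on a protein are scored by their bit score relative to
    the family's curated gathering threshold plus a directional log-odds
    context score for every ordered domain pair, estimated from a directed
    family-pair count network with Dirichlet smoothing. The highest-scoring
    conflict-free subset is found exactly by iterative positive elimination
    followed by an integer linear program with tight AND-constraint
    linearization and greedy clique-cover conflict constraints, solved by a
    built-in exact branch-and-bound. Includes the Standard Pfam baseline
    filter, a first-order Markov context score for comparison, a
    macro-averaged false discovery rate estimator with reversed-sequence
    decoy labeling, a synthetic instance generator, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
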