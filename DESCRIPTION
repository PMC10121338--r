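Package: wigamine
Title: Discriminative Pattern Mining on Individual-Specific Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one weighted gene association network per individual from a
    two-class expression matrix, using a single-observation maximum-likelihood
    correlation ("strength") and a conditional tail probability ("relevance")
    to score and filter edges.  Mines the two resulting network populations for
    top-k maximal discriminative graph patterns ranked by an information-gain
    score, with an admissible upper bound for search-space pruning and a
    brute-force reference miner for verification.  Includes downstream pattern
    summaries (global-view union graph, gene co-occurrence frequencies,
    protein-interaction hub flagging), a block-correlation multivariate-normal
    simulator with planted differentially co-expressed modules, and tidy
    tabular interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
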