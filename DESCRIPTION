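Package: latentmap
Title: Latent-Entropy and Latent-Dimension Maps for Time-Resolved Image Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise pattern discovery in time-resolved image stacks via
    non-parametric latent-Markov factorization of each pixel's transition
    statistics. For every candidate latent dimension K the empirical
    transition law is reduced by direct Bayesian model reduction (hard
    assignment of observed categories to K latent states with closed-form
    emission updates), scored by a corrected Akaike information criterion,
    and model-averaged with posterior weights into two per-pixel measures:
    the latent entropy (predictability of the dynamics) and the latent
    dimension (memory of the dynamics). Includes a two-state falling-toast
    toy model, a synthetic video generator with known hidden structure
    (capillary-like masks, parameter gradients, observation noise), and
    readers/writers for multi-page TIFF stacks and per-pixel measure maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
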