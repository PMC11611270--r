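# Small in-code fixtures shared across test files.

# minimal two-layer experiment: 2 genes x 4 cells, one duration
make_toy_experiment <- function() {
    new <- matrix(c(1L, 0L, 2L, 1L,
                    3L, 1L, 0L, 2L), nrow = 2, byrow = TRUE)
    total <- new + matrix(c(4L, 2L, 1L, 3L,
                            2L, 5L, 3L, 1L), nrow = 2, byrow = TRUE)
    LabelingExperiment(list(new = new, total = total),
                       labelingTime = rep(1, 4))
}

# multi-duration CSP experiment with known rates, unit size factors
make_csp_experiment <- function(nGenes = 3, cellsPerDuration = 200,
                                durations = c(0.5, 1, 2),
                                alpha = 2, gamma_t = 0.8, seed = 42) {
    t <- rep(durations, each = cellsPerDuration)
    n <- length(t)
    withr::with_seed(seed, {
        L <- t(vapply(seq_len(nGenes), function(g)
            rcsp(n, rep(1, n), meanNewBaseline(alpha, gamma_t, t)),
            integer(n)))
        R <- L + t(vapply(seq_len(nGenes), function(g)
            rpois(n, 5), integer(n)))
    })
    le <- LabelingExperiment(list(new = L, total = R), labelingTime = t)
    le$size_factor <- rep(1, n)
    le
}
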