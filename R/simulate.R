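#' Gillespie simulation of the labeling process
#'
#' Exact stochastic simulation (direct-method SSA) of one gene in many
#' cells, with metabolic labeling: molecules transcribed during the final
#' \code{t_label} window carry a label flag, while degradation (and
#' splicing, in the splicing model) act identically on labeled and
#' unlabeled molecules. Transcription runs at rate \code{alpha} until
#' \code{t_switch} (default never) and is silent afterwards, which
#' emulates an induction-then-off gene.
#'
#' @param model \code{"baseline"} (returns new \code{l} and total
#'   \code{r}) or \code{"splicing"} (returns \code{uu}, \code{ul},
#'   \code{su}, \code{sl}).
#' @param alpha transcription rate (scalar or per-cell vector).
#' @param gamma_t total-mRNA degradation rate (baseline model).
#' @param beta,gamma_s splicing and spliced-degradation rates (splicing
#'   model).
#' @param t_obs per-cell observation time (hours).
#' @param t_label per-cell labeling duration, \code{t_label <= t_obs}.
#' @param t_switch transcription shut-off time (default \code{Inf}).
#' @param seed optional integer seed (local RNG scope).
#' @return Integer matrix, one row per cell.
#' @examples
#' gillespieLabel("baseline", alpha = 2, gamma_t = 1,
#'                t_obs = rep(1, 5), t_label = 1, seed = 1)
#' @export
gillespieLabel <- function(model = c("baseline", "splicing"), alpha,
                           gamma_t = NULL, beta = NULL, gamma_s = NULL,
                           t_obs, t_label, t_switch = Inf, seed = NULL) {
    model <- match.arg(model)
    n <- length(t_obs)
    t_label <- rep(t_label, length.out = n)
    if (any(t_label > t_obs))
        stop("t_label must not exceed t_obs", call. = FALSE)
    t_switch <- rep(t_switch, length.out = n)
    .with_seed(seed, {
        if (model == "baseline") {
            stopifnot(!is.null(gamma_t))
            .ssa_baseline(as.numeric(alpha), as.numeric(gamma_t),
                          as.numeric(t_obs), as.numeric(t_label),
                          as.numeric(t_switch))
        } else {
            stopifnot(!is.null(beta), !is.null(gamma_s))
            .ssa_splicing(as.numeric(alpha), as.numeric(beta),
                          as.numeric(gamma_s), as.numeric(t_obs),
                          as.numeric(t_label), as.numeric(t_switch))
        }
    })
}

#' Direct sampler of the cell-specific distributions
#'
#' Draws measured counts from the closed-form laws (CSP, ICSP, CSZIP) at a
#' fixed labeling duration; the fast alternative to the Gillespie
#' simulator for distribution-level tests and estimator calibration.
#'
#' @param model \code{"csp"}, \code{"icsp"} or \code{"cszip"}.
#' @param params list with \code{alpha} and, per model, \code{gamma_t},
#'   \code{beta}, \code{gamma_s}, \code{p_off}.
#' @param p per-cell size factors (length = number of cells).
#' @param t labeling duration: scalar or per-cell.
#' @param seed optional integer seed.
#' @return Vector of counts (CSP/CSZIP) or two-column matrix (ICSP).
#' @export
sampleDistribution <- function(model = c("csp", "icsp", "cszip"), params,
                               p, t, seed = NULL) {
    model <- match.arg(model)
    n <- length(p)
    t <- rep(t, length.out = n)
    switch(model,
        csp = {
            a <- meanNewBaseline(params$alpha, params$gamma_t, t)
            rcsp(n, p, a, seed = seed)
        },
        icsp = {
            bc <- meanNewSplicing(params$alpha, params$beta,
                                  params$gamma_s, t)
            ricsp(n, p, bc$b, bc$c, seed = seed)
        },
        cszip = {
            a <- meanNewBaseline(params$alpha, params$gamma_t, t)
            rcszip(n, p, a, params$p_off, seed = seed)
        })
}

# piecewise-linear three-branch tree interpolation of latent factors:
# trunk root -> mid on [0, T/2], then branch mid -> tip_b on [T/2, T]
.evf_factors <- function(time, branch, anchors, T, jitter_sd) {
    d <- ncol(anchors$root)
    n <- length(time)
    F <- matrix(0, n, d)
    half <- T / 2
    for (i in seq_len(n)) {
        if (time[i] <= half) {
            w <- time[i] / half
            base <- (1 - w) * anchors$root + w * anchors$mid
        } else {
            w <- (time[i] - half) / half
            tip <- if (branch[i] == 1) anchors$tip1 else anchors$tip2
            base <- (1 - w) * anchors$mid + w * tip
        }
        F[i, ] <- base
    }
    F + matrix(rnorm(n * d, sd = jitter_sd), n, d)
}

#' Simulate a bifurcating one-shot labeling experiment
#'
#' Generates the one-shot validation design: a common progenitor branch
#' followed by two fates. Half the cells take observation times uniform on
#' \eqn{[t_l, T/2]} (trunk); the remaining half split equally between two
#' branches with times uniform on \eqn{[T/2, T]}. Cell-gene transcription
#' rates arise from latent extrinsic-variability factors: per-cell factor
#' vectors are interpolated along a piecewise-linear three-branch tree
#' with Gaussian jitter, and \eqn{\alpha_{ij} = \exp(\mathrm{scale}\cdot
#' \langle f_j, e_i\rangle)} clipped to \code{alphaRange}. Gene-wise rates
#' are drawn \eqn{\beta \sim U[0, 0.5]} and \eqn{\gamma_s \sim U[0, 5]}.
#' Counts come from the exact Gillespie simulator of the splicing model
#' with label window \code{t_l}; no technical noise is added, so all size
#' factors are 1.
#'
#' @param nCells,nGenes dimensions (defaults 1000 x 50).
#' @param T max observation time, hours (default 2).
#' @param t_l labeling duration, hours (default 0.4; must be < T/2).
#' @param factorDim latent factor dimension (default 5).
#' @param effectScale gene-effect scale (default 0.5).
#' @param jitterSd factor jitter standard deviation (default 0.15).
#' @param alphaRange clip range for \eqn{\alpha_{ij}} (default
#'   \code{c(0.5, 20)}).
#' @param seed integer seed (required for reproducibility).
#' @return List: \code{experiment} (a \code{LabelingExperiment} with
#'   uu/ul/su/sl layers, size factors 1), \code{truth} (list with
#'   \code{alpha} gene x cell matrix, \code{beta}, \code{gamma_s},
#'   \code{branch}, \code{time}).
#' @export
simulateOneshotBifurcation <- function(nCells = 1000, nGenes = 50, T = 2,
                                       t_l = 0.4, factorDim = 5,
                                       effectScale = 0.5, jitterSd = 0.15,
                                       alphaRange = c(0.5, 20),
                                       seed = 1) {
    if (T / 2 <= t_l) stop("need t_l < T/2", call. = FALSE)
    .with_seed(seed, {
        n1 <- floor(nCells / 2)
        n2 <- floor((nCells - n1) / 2)
        n3 <- nCells - n1 - n2
        branch <- c(rep(0L, n1), rep(1L, n2), rep(2L, n3))
        time <- c(runif(n1, t_l, T / 2), runif(n2 + n3, T / 2, T))
        anchors <- list(root = matrix(rnorm(factorDim), 1),
                        mid = matrix(rnorm(factorDim), 1),
                        tip1 = matrix(rnorm(factorDim, sd = 1.5), 1),
                        tip2 = matrix(rnorm(factorDim, sd = 1.5), 1))
        F <- .evf_factors(time, pmax(branch, 1L), anchors, T, jitterSd)
        E <- matrix(rnorm(nGenes * factorDim), nGenes)
        alpha <- exp(effectScale * tcrossprod(E, F))   # genes x cells
        alpha <- pmin(pmax(alpha, alphaRange[1]), alphaRange[2])
        beta <- runif(nGenes, 0, 0.5)
        gamma_s <- runif(nGenes, 0, 5)
        layers <- lapply(c("uu", "ul", "su", "sl"), function(x)
            matrix(0L, nGenes, nCells))
        names(layers) <- c("uu", "ul", "su", "sl")
        for (g in seq_len(nGenes)) {
            cnt <- .ssa_splicing(alpha[g, ], rep(beta[g], nCells),
                                 rep(gamma_s[g], nCells), time,
                                 rep(t_l, nCells), rep(Inf, nCells))
            for (l in colnames(cnt)) layers[[l]][g, ] <- cnt[, l]
        }
        le <- LabelingExperiment(layers, labelingTime = rep(t_l, nCells))
        le$size_factor <- rep(1, nCells)
        list(experiment = le,
             truth = list(alpha = alpha, beta = beta, gamma_s = gamma_s,
                          branch = branch, time = time))
    })
}

#' Simulate a non-steady-state pulse (kinetics) labeling experiment
#'
#' Generates the multi-duration validation design: gene-wise
#' \eqn{\alpha \sim U[0.5, 1]} and \eqn{\gamma_t \sim U[0, 0.5]}, with
#' each gene transcribing until its switching time \eqn{t_s = 0.5\rho /
#' \gamma_t} (\eqn{\rho \sim U[0, 1]}) and silent afterwards, so the
#' population is away from steady state. Cells take observation times
#' uniform on \eqn{[t_K, T]} and labeling durations drawn with equal
#' probability from the duration set. Counts come from the exact
#' Gillespie simulator of the baseline model; size factors are 1.
#'
#' @param nCells,nGenes dimensions (defaults 2000 x 50).
#' @param T max observation time, hours (default 2, so the observation
#'   window is commensurate with typical switching times and the snapshot
#'   is genuinely away from steady state).
#' @param durations labeling duration set, hours (default
#'   \code{c(0.25, 0.5, 0.75, 1)}).
#' @param seed integer seed.
#' @return List: \code{experiment} (\code{LabelingExperiment} with new and
#'   total layers), \code{truth} (\code{alpha}, \code{gamma_t},
#'   \code{t_s} per gene; \code{time} per cell).
#' @export
simulateKineticsPulse <- function(nCells = 2000, nGenes = 50, T = 2,
                                  durations = c(0.25, 0.5, 0.75, 1),
                                  seed = 1) {
    tK <- max(durations)
    if (tK >= T) stop("max duration must be < T", call. = FALSE)
    .with_seed(seed, {
        alpha <- runif(nGenes, 0.5, 1)
        gamma_t <- runif(nGenes, 0, 0.5)
        rho <- runif(nGenes)
        t_s <- 0.5 * rho / pmax(gamma_t, 1e-12)
        time <- runif(nCells, tK, T)
        tl <- sample(durations, nCells, replace = TRUE)
        L <- R <- matrix(0L, nGenes, nCells)
        for (g in seq_len(nGenes)) {
            cnt <- .ssa_baseline(rep(alpha[g], nCells),
                                 rep(gamma_t[g], nCells), time, tl,
                                 rep(t_s[g], nCells))
            L[g, ] <- cnt[, "l"]; R[g, ] <- cnt[, "r"]
        }
        le <- LabelingExperiment(list(new = L, total = R),
                                 labelingTime = tl)
        le$size_factor <- rep(1, nCells)
        list(experiment = le,
             truth = list(alpha = alpha, gamma_t = gamma_t, t_s = t_s,
                          time = time))
    })
}
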