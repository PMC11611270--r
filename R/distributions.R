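# (1 - exp(-x))/x, stable at small x
.phi <- function(x) {
    out <- ifelse(x == 0, 1, -expm1(-x) / x)
    small <- abs(x) < 1e-8 & x != 0
    if (any(small)) out[small] <- 1 - x[small] / 2 + x[small]^2 / 6
    out
}

#' Mean new-mRNA trajectory of the baseline model
#'
#' Expected number of new (labeled) transcripts after labeling for time
#' \eqn{t} under constant transcription \eqn{\alpha} and first-order
#' degradation \eqn{\gamma_t}:
#' \deqn{a(t) = \alpha (1 - e^{-\gamma_t t}) / \gamma_t,}
#' with the \eqn{\gamma_t = 0} limit \eqn{\alpha t}. This is the Poisson
#' mean of the true new-mRNA count solving the birth-death chemical master
#' equation started from zero molecules.
#'
#' @param alpha transcription rate (molecules/hour), >= 0.
#' @param gamma_t total-mRNA degradation rate (1/hour), >= 0.
#' @param t labeling duration (hours), >= 0. Arguments are vectorized.
#' @return \eqn{a(t)}.
#' @examples
#' meanNewBaseline(2, 0.5, 2)   # 4 * (1 - exp(-1))
#' @export
meanNewBaseline <- function(alpha, gamma_t, t) {
    if (any(alpha < 0) || any(gamma_t < 0) || any(t < 0))
        stop("alpha, gamma_t and t must be >= 0", call. = FALSE)
    alpha * t * .phi(gamma_t * t)
}

#' Mean labeled unspliced/spliced trajectories of the splicing model
#'
#' Expected labeled unspliced and spliced counts under transcription
#' \eqn{\alpha}, splicing \eqn{\beta} and spliced degradation
#' \eqn{\gamma_s}, started from zero:
#' \deqn{b(t) = \alpha (1 - e^{-\beta t}) / \beta}
#' \deqn{c(t) = \frac{\alpha}{\gamma_s}(1 - e^{-\gamma_s t}) +
#'   \frac{\alpha}{\gamma_s - \beta}(e^{-\gamma_s t} - e^{-\beta t})}
#' with the equal-rate branch \eqn{c(t) = \alpha(1-e^{-\beta t})/\beta -
#'   \alpha t e^{-\beta t}} used when \eqn{|\beta - \gamma_s| <
#'   \tau \max(\beta, \gamma_s)} (\code{tol}); outside that band the general
#' branch is evaluated in a cancellation-safe form, so the function is
#' continuous across the boundary.
#'
#' @param alpha,beta,gamma_s rates, >= 0.
#' @param t labeling duration (hours), >= 0.
#' @param tol relative switching tolerance for the equal-rate branch.
#' @return List with components \code{b} and \code{c}.
#' @examples
#' meanNewSplicing(1, 1, 1, 1)   # b = 1 - e^-1, c = 1 - 2 e^-1
#' @export
meanNewSplicing <- function(alpha, beta, gamma_s, t, tol = 1e-8) {
    if (any(alpha < 0) || any(beta < 0) || any(gamma_s < 0) || any(t < 0))
        stop("alpha, beta, gamma_s and t must be >= 0", call. = FALSE)
    b <- alpha * t * .phi(beta * t)
    d <- beta - gamma_s
    equal <- abs(d) < tol * pmax(beta, gamma_s)
    # general branch rewritten as
    #   c = alpha * t * phi(gamma_s t) - alpha * t * e^{-beta t} *
    #       expm1(d t)/(d t)
    # which has no cancellation and tends to the equal-rate branch as d -> 0
    ratio <- ifelse(d == 0 | t == 0, 1, expm1(d * t) / (d * t))
    cc <- alpha * t * .phi(gamma_s * t) - alpha * t * exp(-beta * t) * ratio
    if (any(equal)) {
        ce <- alpha * t * .phi(beta * t) - alpha * t * exp(-beta * t)
        cc[equal] <- ce[equal]
    }
    list(b = b, c = cc)
}

#' Cell-specific Poisson (CSP) log-probability
#'
#' The measured new-mRNA count of cell \eqn{j} is Poisson with mean
#' \eqn{p_j a}, where \eqn{p_j} is the cell's capture probability (size
#' factor) and \eqn{a} the mean true count. Computation is in log space.
#'
#' @param n observed count(s), non-negative integers.
#' @param p size factor(s), > 0.
#' @param a mean parameter \eqn{a(t)}, >= 0.
#' @param log if \code{FALSE}, return the probability itself.
#' @return log-PMF (or PMF) values.
#' @examples
#' dcsp(0, 1, 1)   # -1
#' @export
dcsp <- function(n, p, a, log = TRUE) {
    if (any(n < 0) || any(n != round(n))) stop("n must be a non-negative integer",
                                               call. = FALSE)
    if (any(!is.finite(p)) || any(p <= 0)) stop("p must be finite and > 0",
                                                call. = FALSE)
    out <- dpois(n, p * a, log = TRUE)
    if (log) out else exp(out)
}

#' @rdname dcsp
#' @param nDraws number of samples.
#' @param seed optional integer seed; when given the draw is made in a local
#'   RNG scope that does not disturb the global stream.
#' @export
rcsp <- function(nDraws, p, a, seed = NULL) {
    .with_seed(seed, rpois(nDraws, rep(p, length.out = nDraws) * a))
}

#' Independent cell-specific Poisson (ICSP) log-probability
#'
#' Joint law of the measured labeled unspliced (\code{m}) and spliced
#' (\code{n}) counts: independent Poissons with means \eqn{p_j b} and
#' \eqn{p_j c}.
#'
#' @param m,n observed unspliced/spliced counts.
#' @param p size factor(s), > 0.
#' @param b,c mean parameters, >= 0.
#' @param log if \code{FALSE}, return the probability.
#' @return log-PMF (or PMF) values.
#' @export
dicsp <- function(m, n, p, b, c, log = TRUE) {
    out <- dcsp(m, p, b) + dcsp(n, p, c)
    if (log) out else exp(out)
}

#' @rdname dicsp
#' @param nDraws number of samples.
#' @param seed optional integer seed.
#' @return For \code{ricsp}, a two-column matrix (\code{ul}, \code{sl}).
#' @export
ricsp <- function(nDraws, p, b, c, seed = NULL) {
    p <- rep(p, length.out = nDraws)
    .with_seed(seed, cbind(ul = rpois(nDraws, p * b),
                           sl = rpois(nDraws, p * c)))
}

#' Cell-specific zero-inflated Poisson (CSZIP) log-probability
#'
#' Law of the measured new-mRNA count under slow promoter switching: with
#' probability \eqn{p_{off}} the gene is silent (count 0), otherwise the
#' count is CSP with mean \eqn{p_j a}:
#' \deqn{P(0) = p_{off} + (1 - p_{off}) e^{-p_j a}, \quad
#'       P(n) = (1 - p_{off}) \mathrm{Pois}(n; p_j a), \ n \ge 1.}
#'
#' @param n observed count(s).
#' @param p size factor(s), > 0.
#' @param a mean parameter, >= 0.
#' @param p_off off-state probability in [0, 1].
#' @param log if \code{FALSE}, return the probability.
#' @return log-PMF (or PMF) values.
#' @examples
#' dcszip(0, 1, 1, 0.5, log = FALSE)   # 0.5 * exp(-1) + 0.5
#' @export
dcszip <- function(n, p, a, p_off, log = TRUE) {
    if (any(p_off < 0) || any(p_off > 1))
        stop("p_off must lie in [0, 1]", call. = FALSE)
    lp <- dcsp(n, p, a) + log1p(-p_off)
    zero <- n == 0
    if (any(zero)) {
        # log(p_off + (1 - p_off) e^{-pa}) via pairwise logsumexp
        la <- rep(log(p_off), length.out = length(lp))[zero]
        lb <- lp[zero]
        mx <- pmax(la, lb)
        v <- ifelse(is.infinite(mx) & mx < 0, -Inf,
                    mx + log(exp(la - mx) + exp(lb - mx)))
        lp[zero] <- v
    }
    if (log) lp else exp(lp)
}

#' @rdname dcszip
#' @param nDraws number of samples.
#' @param seed optional integer seed.
#' @export
rcszip <- function(nDraws, p, a, p_off, seed = NULL) {
    p <- rep(p, length.out = nDraws)
    .with_seed(seed, {
        on <- runif(nDraws) >= p_off
        ifelse(on, rpois(nDraws, p * a), 0L)
    })
}

# evaluate expr under a temporary seed without clobbering the caller's RNG
.with_seed <- function(seed, expr) {
    expr <- substitute(expr)
    if (is.null(seed)) return(eval(expr, parent.frame()))
    has <- exists(".Random.seed", globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, globalenv())
        else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval(expr, parent.frame())
}
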