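# Shared numerical helpers.

#' Per-cell normalized expression
#'
#' Counts-per-10,000 per cell followed by log1p; the normalization used for
#' expression statistics (HVG selection, embeddings, marker dot plots).
#'
#' @param x a [MesoCounts-class] object.
#' @param scale library-size scale factor (default 1e4).
#' @return genes x cells dense matrix of log1p(CP10K).
#' @export
logNormCounts <- function(x, scale = 1e4) {
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    tot <- colSums(cts)
    tot[tot == 0] <- 1
    log1p(sweep(cts, 2, tot, "/") * scale)
}

# Median-library size factors (relative depth); genes x cells counts in.
sizeFactors_ <- function(cts) {
    tot <- colSums(cts)
    tot / stats::median(tot)
}

#' Latent linear-ODE trajectories
#'
#' Closed-form solution of `dz/dt = A z`, `z(0) = z0`, evaluated at the
#' requested times via the eigendecomposition of `A` (real part taken for
#' complex conjugate pairs). Used both to drive the cell simulator and as
#' the self-consistency reference for the generated trajectories.
#'
#' @param A square coefficient matrix.
#' @param z0 initial state.
#' @param times numeric vector of evaluation times.
#' @return length(z0) x length(times) matrix of states.
#' @export
odeTrajectory <- function(A, z0, times) {
    eig <- eigen(A)
    V <- eig$vectors
    out <- tryCatch({
        c0 <- solve(V, as.complex(z0))
        vapply(times, function(t)
            Re(V %*% (exp(eig$values * t) * c0))[, 1],
            numeric(length(z0)))
    }, error = function(e)
        # defective A (repeated eigenvalues): matrix exponential per time
        vapply(times, function(t)
            as.numeric(Matrix::expm(A * t) %*% z0), numeric(length(z0))))
    dimnames(out) <- list(rownames(A), NULL)
    out
}

#' Consensus string of a PWM
#'
#' @param pwm a [Pwm-class] object.
#' @param degenerate character used for near-uniform positions.
#' @return character(1) consensus.
#' @export
pwmConsensus <- function(pwm, degenerate = "n") {
    apply(pwm@mat, 1, function(p) {
        if (max(p) < 0.5) degenerate else c("A", "C", "G", "T")[which.max(p)]
    }) |> paste(collapse = "")
}

# Deterministic seed substreams: small offsets keep derived seeds < 2^31.
subSeed <- function(seed, k) (as.integer(seed) + 1000L * as.integer(k)) %% 2147483647L

# Ordered unique pair key for undirected edge sets.
pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}
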