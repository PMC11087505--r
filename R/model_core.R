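#' Expected ALT-allele fraction per donor and SNP
#'
#' Looks up the allele-frequency parameter for each donor's genotype
#' category: mu[i, k] = theta_t where t in {0, 1, 2} is donor k's category at
#' SNP i. This is the per-donor emission rate of ALT reads that the mixture
#' model averages with the donor proportions.
#'
#' @param G a [genotype_matrix()] with no missing entries (run
#'   [filter_effective_variants()] first).
#' @param theta allele-frequency parameters, see [check_theta()].
#' @return numeric N x K matrix mu.
#' @export
donor_allele_means <- function(G, theta = c(0.01, 0.5, 0.99)) {
  theta <- check_theta(theta)
  if (anyNA(G$G)) stop("genotype matrix has missing entries; filter first")
  mu <- matrix(theta[G$G + 1L], nrow = nrow(G$G), ncol = ncol(G$G))
  colnames(mu) <- G$donors
  mu
}

#' Pooled-sample log-likelihood
#'
#' Each read at SNP i is ALT with probability mu_i' phi (the donor-averaged
#' ALT rate), so the pooled counts are binomial and the log-likelihood is
#' sum_i \[a_i log(mu_i' phi) + (d_i - a_i) log(1 - mu_i' phi)\]. The
#' binomial coefficient, constant in phi, is omitted, so traces are
#' comparable across fits but not across data sets. Mixture rates falling
#' outside (0, 1) by rounding are clamped to \[1e-12, 1 - 1e-12\].
#'
#' @param counts an [allelic_counts()].
#' @param mu N x K matrix from [donor_allele_means()].
#' @param phi donor proportions on the simplex.
#' @return scalar log-likelihood.
#' @export
pool_loglik <- function(counts, mu, phi) {
  phi <- check_phi(phi, K = ncol(mu))
  stopifnot(length(counts$a) == nrow(mu))
  p <- as.vector(mu %*% phi)
  eps <- 1e-12
  n_clamped <- sum(p < eps | p > 1 - eps)
  if (n_clamped > 0L) {
    p <- pmin(pmax(p, eps), 1 - eps)
    message(n_clamped, " SNP mixture rates clamped to [1e-12, 1-1e-12]")
  }
  sum(counts$a * log(p) + (counts$d - counts$a) * log1p(-p))
}

#' Fit donor proportions by expectation-maximization
#'
#' Maximum-likelihood estimation of the donor proportions phi (and,
#' optionally, the allele-frequency vector theta) under the binomial mixture
#' over donor genotypes. The E-step assigns each ALT read at SNP i to donor
#' k with responsibility proportional to phi_k * mu\[i,k\], and each REF read
#' proportional to phi_k * (1 - mu\[i,k\]); the M-step sets phi_k to that
#' donor's share of the total read mass. With `theta_mode = "adaptive"`,
#' theta_t is re-estimated as the ALT fraction of the read mass assigned to
#' donor-SNP pairs with genotype category t, clipped to \[1e-4, 1 - 1e-4\]
#' and re-sorted to keep theta0 < theta1 < theta2 (resolving label
#' switching).
#'
#' Iteration stops when the log-likelihood improves by less than `tol` or at
#' `max_iter`. The algorithm is deterministic given its inputs: phi starts
#' uniform at 1/K and theta at `theta0`.
#'
#' @param counts an [allelic_counts()], already restricted to effective SNPs.
#' @param G the aligned [genotype_matrix()] (no missing entries).
#' @param theta_mode `"fixed"` holds theta at `theta0`; `"adaptive"` learns it.
#' @param theta0 initial (or fixed) allele-frequency parameters.
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter iteration cap.
#' @return an object of class `demux_fit`: `phi` (named by donor), `theta`,
#'   `loglik_trace` (one entry per iteration, non-decreasing), `n_iter`,
#'   `converged`.
#' @export
em_fit <- function(counts, G, theta_mode = c("fixed", "adaptive"),
                   theta0 = c(0.01, 0.5, 0.99), tol = 1e-6,
                   max_iter = 1000L) {
  theta_mode <- match.arg(theta_mode)
  theta <- check_theta(theta0)
  stop_if_misaligned(G, counts)
  if (anyNA(G$G)) stop("genotype matrix has missing entries; filter first")
  K <- length(G$donors)
  if (K == 1L) {
    mu <- donor_allele_means(G, theta)
    ll <- suppressMessages(pool_loglik(counts, mu, 1))
    return(structure(list(phi = stats::setNames(1, G$donors), theta = theta,
                          loglik_trace = ll, n_iter = 0L, converged = TRUE),
                     class = "demux_fit"))
  }

  a <- counts$a; b <- counts$d - counts$a; dtot <- sum(counts$d)
  if (dtot == 0) stop("no reads at the effective SNPs")
  phi <- rep(1 / K, K)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  eps <- 1e-12
  it <- 0L

  Gcat <- G$G
  repeat {
    it <- it + 1L
    mu <- matrix(theta[Gcat + 1L], nrow = nrow(Gcat), ncol = K)

    # E-step: read-origin responsibilities per SNP and allele class
    WA <- sweep(mu, 2L, phi, "*")
    WB <- sweep(1 - mu, 2L, phi, "*")
    rA <- WA / pmax(rowSums(WA), eps)
    rB <- WB / pmax(rowSums(WB), eps)

    # M-step: donor proportions as each donor's share of the read mass
    massA <- a * rA
    massB <- b * rB
    phi <- (colSums(massA) + colSums(massB)) / dtot
    phi <- pmax(phi, 0); phi <- phi / sum(phi)

    if (theta_mode == "adaptive") {
      for (t in 0:2) {
        m <- Gcat == t
        tot <- sum(massA[m]) + sum(massB[m])
        if (tot > 0) theta[t + 1L] <- sum(massA[m]) / tot
      }
      theta <- sort(pmin(pmax(theta, 1e-4), 1 - 1e-4))
    }

    mu <- matrix(theta[Gcat + 1L], nrow = nrow(Gcat), ncol = K)
    p <- pmin(pmax(as.vector(mu %*% phi), eps), 1 - eps)
    ll <- sum(a * log(p) + b * log1p(-p))
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll
  }

  structure(list(phi = stats::setNames(phi, G$donors), theta = theta,
                 loglik_trace = trace, n_iter = it, converged = converged),
            class = "demux_fit")
}

#' @export
print.demux_fit <- function(x, ...) {
  cat(sprintf("demux_fit: K=%d donors, %d EM iterations (%s)\n",
              length(x$phi), x$n_iter,
              if (x$converged) "converged" else "iteration cap"))
  cat("phi:  ", paste(sprintf("%s=%.4f", names(x$phi), x$phi),
                      collapse = "  "), "\n")
  cat(sprintf("theta: (%.4f, %.4f, %.4f)   logLik: %.3f\n",
              x$theta[1], x$theta[2], x$theta[3],
              x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' Exhaustive simplex grid search for donor proportions
#'
#' Independent maximizer of the pooled log-likelihood by scanning the
#' probability simplex on a regular grid, then refining around the incumbent
#' on a 10x finer grid. Only practical for K = 2 or 3; intended as a
#' reference against which the EM fit can be validated on small instances
#' (the log-likelihood is concave in phi, so the local refinement is exact).
#'
#' @param counts,G as in [em_fit()].
#' @param theta fixed allele-frequency parameters.
#' @param step coarse grid resolution (default 1e-3).
#' @param refine refine around the coarse optimum at `step/10` (default TRUE).
#' @return list with `phi` and `loglik`.
#' @export
grid_search_phi <- function(counts, G, theta = c(0.01, 0.5, 0.99),
                            step = 1e-3, refine = TRUE) {
  K <- length(G$donors)
  if (!K %in% c(2L, 3L)) stop("grid search supports K = 2 or 3 only")
  mu <- donor_allele_means(G, theta)
  a <- counts$a; b <- counts$d - counts$a
  eps <- 1e-12
  ll_of <- function(PHI) {            # PHI: K x M candidate matrix
    P <- pmin(pmax(mu %*% PHI, eps), 1 - eps)
    as.vector(crossprod(log(P), a) + crossprod(log1p(-P), b))
  }
  scan <- function(lo, hi, by) {
    g1 <- seq(max(lo[1], 0), min(hi[1], 1), by = by)
    if (K == 2L) {
      PHI <- rbind(g1, 1 - g1)
      cand <- PHI
    } else {
      g2 <- seq(max(lo[2], 0), min(hi[2], 1), by = by)
      grid <- expand.grid(p1 = g1, p2 = g2)
      grid <- grid[grid$p1 + grid$p2 <= 1 + 1e-12, ]
      cand <- t(cbind(grid$p1, grid$p2, pmax(1 - grid$p1 - grid$p2, 0)))
    }
    best <- -Inf; best_phi <- NULL
    idx <- split(seq_len(ncol(cand)),
                 ceiling(seq_len(ncol(cand)) / 50000))
    for (ix in idx) {
      lls <- ll_of(cand[, ix, drop = FALSE])
      j <- which.max(lls)
      if (lls[j] > best) { best <- lls[j]; best_phi <- cand[, ix[j]] }
    }
    list(phi = best_phi, loglik = best)
  }
  coarse <- scan(rep(0, K), rep(1, K), step)
  if (!refine) return(coarse)
  fine <- scan(coarse$phi - 2 * step, coarse$phi + 2 * step, step / 10)
  if (fine$loglik >= coarse$loglik) fine else coarse
}
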