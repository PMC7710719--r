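#' Iterative correction (ICE) of a contact matrix
#'
#' Multiplicative per-bin correction that equalizes the marginals of the
#' valid submatrix.  Bins whose raw marginal falls below `filter_frac` of the
#' mean marginal are masked before correction (low-coverage filter), and
#' all-zero valid rows are auto-masked with a warning.
#'
#' @param m a `contact_matrix`.
#' @param tol convergence tolerance: coefficient of variation of the valid
#'   marginals.
#' @param max_iter iteration cap; non-convergence is reported with the
#'   achieved CV.
#' @param filter_frac low-coverage mask threshold as a fraction of the mean
#'   marginal (default 2\%).
#' @param algorithm `"kr"` (Knight-Ruiz Newton solver, default) or `"ice"`
#'   (the classic marginal-division iteration).  The equal-marginal scaling
#'   of an irreducible nonnegative matrix is unique, so both algorithms
#'   converge to the same balanced matrix; KR gets there in far fewer
#'   matrix-vector products.
#' @return the balanced `contact_matrix`; `$bias` holds the estimated per-bin
#'   bias b (mean 1 over valid bins) such that
#'   `balanced_ij = raw_ij / (b_i * b_j)`.
#' @export
ice_balance <- function(m, tol = 1e-5, max_iter = 200, filter_frac = 0.02,
                        algorithm = c("kr", "ice")) {
  stopifnot(inherits(m, "contact_matrix"))
  algorithm <- match.arg(algorithm)
  valid <- m$valid
  marg <- rowSums(m$values, na.rm = TRUE)
  zero <- valid & marg == 0
  if (any(zero)) {
    warning(sum(zero), " valid bin(s) with all-zero rows auto-masked")
    valid[zero] <- FALSE
  }
  low <- valid & marg < filter_frac * mean(marg[valid])
  valid[low] <- FALSE
  if (sum(valid) < 2) stop("fewer than 2 valid bins after filtering")

  A <- m$values[valid, valid, drop = FALSE]
  x <- if (algorithm == "kr") kr_scaling(A, tol = tol) else NULL
  if (is.null(x)) {  # classic iteration (also the KR fallback)
    W <- A
    b <- rep(1, nrow(W))
    cv <- Inf
    iters <- if (algorithm == "kr") max(max_iter, 3000) else max_iter
    for (it in seq_len(iters)) {
      s <- rowSums(W)
      cv <- stats::sd(s) / mean(s)
      if (is.finite(cv) && cv < tol) break
      sn <- s / mean(s)
      W <- W / outer(sn, sn)
      b <- b * sn
    }
    if (!is.finite(cv) || cv >= tol)
      warning("balancing did not converge in ", iters,
              " iterations (marginal CV = ", signif(cv, 3), ")")
  } else {
    W <- A * outer(x, x)
    s <- rowSums(W)
    cv <- stats::sd(s) / mean(s)
    if (!is.finite(cv) || cv >= tol)
      warning("balancing did not converge (marginal CV = ", signif(cv, 3), ")")
    b <- 1 / x
  }
  b <- b / mean(b)
  out <- matrix(NA_real_, nrow(m$bins), nrow(m$bins))
  out[valid, valid] <- W * (sum(m$values[valid, valid]) / sum(W))
  res <- contact_matrix(m$bins, out, valid = valid, balanced = TRUE)
  bias <- rep(NA_real_, nrow(m$bins))
  bias[valid] <- b
  res$bias <- bias
  res
}

# Knight-Ruiz matrix balancing: finds x > 0 with diag(x) A diag(x) having
# unit row sums, by an inexact Newton method with conjugate-gradient inner
# iterations.  Returns NULL if the solver leaves the positive cone, in
# which case the caller falls back to the classic iteration.
kr_scaling <- function(A, tol = 1e-5, delta = 0.1, Delta = 3,
                       max_outer = 50) {
  n <- nrow(A)
  A <- A / (sum(A) / n)            # bring row sums near 1 at x = 1
  e <- rep(1, n)
  # target residual: RMS marginal deviation well below tol -> CV < tol
  rt <- (0.5 * tol)^2 * n
  x <- e
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho <- sum(rk * rk)
  rout <- rho
  rold <- rout
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  outer_it <- 0
  while (rout > rt) {
    outer_it <- outer_it + 1
    if (outer_it > max_outer) return(NULL)
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km1 <- rho
    Z <- p <- NULL
    rho_km2 <- 0
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200) break
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho <- sum(rk * rk)
    rout <- rho
    rat <- rout / rold
    rold <- rout
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / sqrt(rout / n + 1e-300))
  }
  x
}

#' Scale a matrix to a fixed total
#'
#' Every entry is multiplied by `total / current total`, the fixed-total
#' normalization (default one million) that makes matrices comparable
#' between conditions.
#'
#' @param m a `contact_matrix` with positive total.
#' @param total target sum, default 1e6.
#' @export
scale_to_total <- function(m, total = 1e6) {
  cur <- matrix_total(m)
  if (!is.finite(cur) || cur <= 0) stop("matrix total must be positive")
  m$values <- m$values * (total / cur)
  m
}

#' Aggregate a matrix to a coarser resolution
#'
#' Counts are summed over groups of consecutive bins; chromosome boundaries
#' are never straddled.  A coarse bin is valid iff at least one constituent
#' bin is valid; contributions from masked constituents are zero.
#'
#' @param m a `contact_matrix`.
#' @param coarser_resolution integer multiple of the current resolution.
#' @export
rebin <- function(m, coarser_resolution) {
  res <- m$resolution
  fac <- coarser_resolution / res
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("coarser_resolution must be an integer multiple of ", res)
  fac <- round(fac)
  if (fac == 1) return(m)
  idx <- chrom_bin_index(m$bins)
  lens <- chrom_lengths_from_bins(m$bins)
  new_bins <- make_bin_table(lens, coarser_resolution, attr(m$bins, "assembly"))
  group <- integer(nrow(m$bins))
  offset <- 0L
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    group[ii] <- offset + ((seq_along(ii) - 1L) %/% fac) + 1L
    offset <- max(group[ii])
  }
  nG <- nrow(new_bins)
  stopifnot(offset == nG)
  G <- matrix(0, nrow(m$bins), nG)
  G[cbind(seq_len(nrow(m$bins)), group)] <- 1
  G[!m$valid, ] <- 0
  V0 <- m$values
  V0[is.na(V0)] <- 0
  V <- t(G) %*% V0 %*% G
  valid <- as.vector(t(G) %*% m$valid) > 0
  V[!valid, ] <- NA_real_
  V[, !valid] <- NA_real_
  out <- contact_matrix(new_bins, V, valid = valid, balanced = m$balanced)
  out
}

#' Entrywise log2 ratio of two matrices
#'
#' `log2((A + eps) / (B + eps))`, masked wherever either input is masked.
#' The default pseudocount is the smallest positive entry across both
#' matrices, which keeps empty cells from dominating the map.
#'
#' @param a,b `contact_matrix` objects on identical bin tables (scale both
#'   to the same total first).
#' @param pseudocount eps added to both numerator and denominator.
#' @return a `ratio_map` (bins + signed values + mask).
#' @export
log2_ratio_map <- function(a, b, pseudocount = NULL) {
  stop_if_bins_differ(a, b)
  if (is.null(pseudocount)) {
    pos <- c(a$values[a$values > 0], b$values[b$values > 0])
    pseudocount <- if (length(pos)) min(pos, na.rm = TRUE) else 1e-9
  }
  valid <- a$valid & b$valid
  V <- log2((a$values + pseudocount) / (b$values + pseudocount))
  V[!valid, ] <- NA_real_
  V[, !valid] <- NA_real_
  structure(list(bins = a$bins, values = V, valid = valid,
                 pseudocount = pseudocount),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat("log2 ratio map:", nrow(x$bins), "bins; pseudocount",
      signif(x$pseudocount, 4), "\n")
  cat("  range:", paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " .. "), "\n")
  invisible(x)
}
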