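#' Per-site pseudo-likelihood objective and gradient
#'
#' Evaluates the weighted negative log-pseudo-likelihood contribution of one
#' alignment column plus its L2 penalty, together with the analytic
#' gradient. Exposed mainly so the gradient can be verified against finite
#' differences; [fitPlm()] uses it internally.
#'
#' @param aln a [CodedAlignment-class].
#' @param w a matching [SequenceWeights-class].
#' @param site column index (1-based).
#' @param par parameter vector of length `q + (L-1)*q^2`: the site fields
#'   h_i followed by the q x q coupling blocks to every other column in
#'   ascending column order (column-major within a block).
#' @param lambdaH,lambdaJ L2 strengths for fields and couplings.
#' @return list with `value` and `gradient`.
#' @export
plmSiteObjective <- function(aln, w, site, par, lambdaH = 0.01,
                             lambdaJ = NULL) {
  L <- alnLength(aln)
  if (is.null(lambdaJ)) lambdaJ <- 0.01 * (L - 1)
  res <- cpp_plm_site(alnCodes(aln), as.integer(site), seqWeights(w),
                      lambdaH, lambdaJ, par)
  list(value = res$value, gradient = as.numeric(res$grad))
}

#' Fit the Potts evolutionary coupling model by pseudo-likelihood
#'
#' Minimizes, independently for every column i, the weighted negative
#' log-pseudo-likelihood sum_s w_s * -log P(a_si | a_s,-i) with L2 penalties
#' lambdaH * ||h_i||^2 + lambdaJ * ||J_i.||^2 using L-BFGS-B from a zero
#' start (deterministic, no seed needed). Weights are not normalized, so the
#' data term scales with Neff; the default lambdaJ = 0.01 * (L - 1) follows
#' the usual pseudo-likelihood DCA convention. The per-site (asymmetric)
#' coupling estimates are reconciled by averaging:
#' J_ij = (Jhat_ij^(i) + t(Jhat_ji^(j))) / 2.
#'
#' @param aln a [CodedAlignment-class] (L >= 2).
#' @param w a matching [SequenceWeights-class] with neff >= 2.
#' @param lambdaH field regularization (default 0.01).
#' @param lambdaJ coupling regularization (default 0.01 * (L - 1)).
#' @param maxIter L-BFGS-B iteration cap per site (default 500).
#' @param tol projected-gradient tolerance (default 1e-5).
#' @param verbose print per-site progress.
#' @return a [PottsModel-class]. Non-convergence within `maxIter` is
#'   recorded per site on the `converged` slot and raised as a warning, not
#'   an error.
#' @export
fitPlm <- function(aln, w, lambdaH = 0.01, lambdaJ = NULL, maxIter = 500L,
                   tol = 1e-5, verbose = FALSE) {
  L <- alnLength(aln); q <- alphabetSize(aln)
  if (L < 2L) stop("alignment length must be >= 2")
  if (neff(w) < 2)
    warning("neff < 2: couplings are driven by regularization only",
            call. = FALSE)
  if (is.null(lambdaJ)) lambdaJ <- 0.01 * (L - 1)
  codes <- alnCodes(aln); ws <- seqWeights(w)
  npar <- q + (L - 1L) * q * q

  h <- matrix(0, L, q)
  J <- array(0, dim = c(L, L, q, q))
  converged <- logical(L)

  for (i in seq_len(L)) {
    ## cache so fn/gr pairs cost one C++ evaluation
    cache <- new.env(parent = emptyenv())
    evalAt <- function(p) {
      if (is.null(cache$par) || !identical(p, cache$par)) {
        cache$res <- cpp_plm_site(codes, i, ws, lambdaH, lambdaJ, p)
        cache$par <- p
      }
      cache$res
    }
    fn <- function(p) evalAt(p)$value
    gr <- function(p) as.numeric(evalAt(p)$grad)
    opt <- optim(numeric(npar), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxIter, pgtol = tol, factr = 1e7))
    if (!all(is.finite(opt$par)) || !is.finite(opt$value))
      stop("non-finite PLM objective at column ", i)
    h[i, ] <- opt$par[seq_len(q)]
    blocks <- array(opt$par[-seq_len(q)], dim = c(q, q, L - 1L))
    others <- setdiff(seq_len(L), i)
    for (k in seq_along(others)) J[i, others[k], , ] <- blocks[, , k]
    converged[i] <- opt$convergence == 0L
    if (verbose) message(sprintf("site %d/%d: nll %.4f (%s)", i, L,
                                 opt$value,
                                 if (converged[i]) "converged" else opt$message))
  }

  ## symmetrize the two independent estimates of each block
  Js <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) {
    for (j in seq((i + 1L), L)) {
      blk <- (J[i, j, , ] + t(J[j, i, , ])) / 2
      Js[i, j, , ] <- blk
      Js[j, i, , ] <- t(blk)
    }
  }
  msg <- if (all(converged)) "all site fits converged" else
    sprintf("%d/%d site fits hit maxIter", sum(!converged), L)
  if (!all(converged))
    warning("PLM: ", msg, call. = FALSE)
  new("PottsModel", h = h, J = Js, lambdaH = lambdaH, lambdaJ = lambdaJ,
      converged = converged, message = msg)
}
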