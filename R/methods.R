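# Standard modelling-object methods for poisdecon fits.

#' @export
print.poisdecon <- function(x, digits = 3L, ...) {
  cat(sprintf("Scaled-Poisson bulk decomposition (%d genes, %d cell types, %d replicate(s))\n",
              length(x$gene_ids), length(x$type_names), ncol(x$composition)))
  cat(sprintf("  %s after %d iteration(s); quasi-log-likelihood %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$loglik_trace[length(x$loglik_trace)]))
  cat("Composition:\n")
  print(round(x$composition, digits))
  invisible(x)
}

#' Summarize a decomposition fit
#'
#' @param object a `poisdecon` fit.
#' @param ... unused.
#' @return an object of class `summary.poisdecon`.
#' @export
summary.poisdecon <- function(object, ...) {
  structure(list(
    composition = object$composition,
    scale = object$scale,
    n_genes = length(object$gene_ids),
    n_types = length(object$type_names),
    n_cells = length(object$reference_scales),
    n_iter = object$n_iter,
    converged = object$converged,
    stalled = object$stalled,
    loglik = object$loglik_trace[length(object$loglik_trace)],
    n_fallback = object$n_fallback,
    precision_range = range(object$T)),
    class = "summary.poisdecon")
}

#' @export
print.summary.poisdecon <- function(x, digits = 3L, ...) {
  cat("Scaled-Poisson bulk decomposition\n")
  cat(sprintf("  genes: %d   cell types: %d   reference cells: %d\n",
              x$n_genes, x$n_types, x$n_cells))
  cat(sprintf("  iterations: %d (%s%s)   quasi-log-likelihood: %.4f\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              if (isTRUE(x$stalled)) ", objective stalled" else "", x$loglik))
  cat(sprintf("  fitted precision range: [%.3g, %.3g]   fallback genes: %d\n",
              x$precision_range[1L], x$precision_range[2L], x$n_fallback))
  cat("Composition (cell types x replicates):\n")
  print(round(x$composition, digits))
  cat("Scale factors:\n")
  print(signif(x$scale, digits))
  invisible(x)
}

#' Fitted cell-type composition
#'
#' @param object a `poisdecon` fit.
#' @param ... unused.
#' @return cell types x replicates matrix; columns sum to 1.
#' @export
coef.poisdecon <- function(object, ...) object$composition

#' @export
logLik.poisdecon <- function(object, ...) {
  m <- length(object$gene_ids); k <- length(object$type_names)
  r <- ncol(object$composition)
  ll <- object$loglik_trace[length(object$loglik_trace)]
  structure(ll,
            df = 2 * m * k + r * (k - 1) + r + length(object$reference_scales),
            nobs = m * (r + length(object$reference_scales)),
            class = "logLik")
}

#' Fitted bulk means
#'
#' @param object a `poisdecon` fit.
#' @param ... unused.
#' @return genes x replicates matrix of fitted means
#'   `sum_l X[i,l] w[l,r] G[r]`.
#' @export
fitted.poisdecon <- function(object, ...) {
  mu <- object$X %*% sweep(object$composition, 2L, object$scale, "*")
  dimnames(mu) <- list(object$gene_ids, colnames(object$composition))
  mu
}

#' Residuals of a decomposition fit
#'
#' @param object a `poisdecon` fit.
#' @param type `"response"` (observed minus fitted) or `"pearson"` (scaled by
#'   the model standard deviation `sqrt(sum_l lambda[l] / t[l])`).
#' @param ... unused.
#' @return genes x replicates matrix.
#' @export
residuals.poisdecon <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  y <- apply(object$allocations, c(1L, 3L), sum)
  mu <- fitted(object)
  res <- y - mu
  if (type == "pearson") {
    v <- matrix(0, nrow(mu), ncol(mu))
    for (r in seq_len(ncol(mu)))
      v[, r] <- rowSums(sweep(object$X / object$T, 2L,
                              object$composition[, r] * object$scale[r], "*"))
    res <- res / sqrt(pmax(v, .Machine$double.xmin))
  }
  dimnames(res) <- dimnames(mu)
  res
}

#' Plot a decomposition fit
#'
#' Left panel: the quasi-log-likelihood trace. Right panel: a stacked barplot
#' of the fitted composition per replicate.
#'
#' @param x a `poisdecon` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.poisdecon <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                 xlab = "iteration", ylab = "quasi-log-likelihood",
                 main = "fit trace")
  graphics::barplot(x$composition, legend.text = rownames(x$composition),
                    ylab = "composition", main = "cell-type composition", ...)
  invisible(x)
}

#' Simulate bulk counts from a fitted decomposition
#'
#' Draws new bulk replicate count vectors from the fitted scaled-Poisson
#' model (latent per-type counts with means `X[i,l] w[l,r] G[r]` and
#' precisions `T[i,l]`, summed per gene).
#'
#' @param object a `poisdecon` fit.
#' @param nsim number of simulated replicate sets.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @param ... unused.
#' @return list of `nsim` genes x replicates matrices.
#' @export
simulate.poisdecon <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    lapply(seq_len(nsim), function(s) {
      R <- ncol(object$composition)
      out <- matrix(0, nrow(object$X), R,
                    dimnames = list(object$gene_ids, colnames(object$composition)))
      for (r in seq_len(R)) {
        lam <- sweep(object$X, 2L,
                     object$composition[, r] * object$scale[r], "*")
        z <- rscaled_pois(length(lam), as.numeric(lam), as.numeric(object$T))
        out[, r] <- rowSums(matrix(z, nrow(object$X)))
      }
      out
    })
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
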