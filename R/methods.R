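#' @export
print.noise2fast <- function(x, ...) {
  tr <- x$trace
  cat("Blind single-image denoising fit (chequerboard self-supervision)\n")
  cat(sprintf("  image: %d x %d, intensity range [%g, %g]\n",
              nrow(x$input), ncol(x$input), min(x$input), max(x$input)))
  if (tr$stopped_reason == "degenerate_input") {
    cat("  constant input: returned unchanged, no training performed\n")
    return(invisible(x))
  }
  cat(sprintf("  iterations: %d (best checkpoint at %d, stopped: %s)\n",
              length(tr$losses), tr$best_iteration, tr$stopped_reason))
  cat(sprintf("  best validation PSNR vs noisy input: %.2f dB\n",
              max(tr$validations$psnr)))
  invisible(x)
}

#' @export
summary.noise2fast <- function(object, ...) {
  tr <- object$trace
  s <- list(
    dim = dim(object$input),
    iterations = length(tr$losses),
    best_iteration = tr$best_iteration,
    stopped_reason = tr$stopped_reason,
    best_validation_psnr = if (nrow(tr$validations)) max(tr$validations$psnr)
                           else NA_real_,
    final_loss = if (length(tr$losses)) tr$losses[length(tr$losses)]
                 else NA_real_,
    residual_sd = stats::sd(object$input - object$denoised),
    downsampling = object$settings$downsampling,
    inference = object$settings$inference,
    n_parameters = if (is.null(object$network)) 0L
                   else n_parameters(object$network))
  class(s) <- "summary.noise2fast"
  s
}

#' @export
print.summary.noise2fast <- function(x, ...) {
  cat("noise2fast denoising summary\n")
  cat(sprintf("  image: %d x %d | training set: %s | inference: %s\n",
              x$dim[1], x$dim[2], x$downsampling, x$inference))
  cat(sprintf("  network parameters: %s\n",
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  iterations: %d, best at %d (stopped: %s)\n",
              x$iterations, x$best_iteration, x$stopped_reason))
  cat(sprintf("  best validation PSNR: %.2f dB | final loss: %.5f\n",
              x$best_validation_psnr, x$final_loss))
  cat(sprintf("  removed-noise SD (input - denoised): %.4g\n", x$residual_sd))
  invisible(x)
}

#' Extract results from a denoising fit
#'
#' `fitted()` returns the denoised image on the original intensity scale;
#' `residuals()` the removed component `input - denoised` (for pure noise
#' removal this should look structureless).
#'
#' @param object a `noise2fast` fit.
#' @param ... unused.
#' @return numeric matrix of the input's shape.
#' @export
fitted.noise2fast <- function(object, ...) object$denoised

#' @rdname fitted.noise2fast
#' @export
residuals.noise2fast <- function(object, ...) object$input - object$denoised

#' @export
coef.noise2fast <- function(object, ...) {
  if (is.null(object$network)) return(list())
  object$network$weights
}

#' Apply the trained network to another image
#'
#' Runs the best-checkpoint network on a new image. The image is min-max
#' normalized on its own range (the network operates in \eqn{[0,1]}) and the
#' output mapped back to that range. Useful for denoising further frames
#' acquired under the same conditions without retraining.
#'
#' @param object a `noise2fast` fit with a trained network.
#' @param newdata numeric matrix; defaults to the training input.
#' @param ... unused.
#' @return denoised matrix on `newdata`'s intensity scale.
#' @export
predict.noise2fast <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$denoised)
  if (is.null(object$network))
    stop_n2f("degenerate fit has no trained network")
  nn <- normalize_image(as_pixel_matrix(newdata))
  if (nn$degenerate) return(as_pixel_matrix(newdata))
  denormalize_image(nn, forward_pass(object$network, nn$pixels))
}

#' Plot the training and validation trace
#'
#' Left panel: per-iteration BCE loss. Right panel: validation PSNR of the
#' network's self-map on the noisy input, with the selected best checkpoint
#' marked; if a ground-truth reference was supplied, its PSNR trace is
#' overlaid, showing the two curves peaking together -- the property the
#' stopping rule relies on.
#'
#' @param x a `noise2fast` fit.
#' @param ... unused.
#' @export
plot.noise2fast <- function(x, ...) {
  tr <- x$trace
  if (!length(tr$losses)) {
    warning("degenerate fit: nothing to plot")
    return(invisible(x))
  }
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(seq_along(tr$losses), tr$losses, type = "l", col = "grey40",
       xlab = "iteration", ylab = "BCE loss", main = "training loss")
  v <- tr$validations
  has_ref <- any(is.finite(v$reference_psnr))
  ylim <- range(c(v$psnr, if (has_ref) v$reference_psnr), finite = TRUE)
  plot(v$iteration, v$psnr, type = "b", pch = 20, col = "steelblue",
       ylim = ylim, xlab = "iteration", ylab = "PSNR (dB)",
       main = "validation trace")
  if (has_ref) {
    lines(v$iteration, v$reference_psnr, type = "b", pch = 1, col = "firebrick")
    legend("bottomright", bty = "n", col = c("steelblue", "firebrick"),
           pch = c(20, 1), legend = c("vs noisy input", "vs ground truth"))
  }
  abline(v = tr$best_iteration, lty = 2)
  invisible(x)
}
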