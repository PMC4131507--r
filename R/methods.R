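# S3 methods shared by fac/lfac fits.

#' @export
print.fuzzy_ac <- function(x, ...) {
  cat(sprintf("%s fit (%d x %d image)\n",
              toupper(x$params$model), x$dim[1], x$dim[2]))
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Iterations: %d (%s%s)\n", x$iterations,
              if (x$converged) "converged: " else "stopped: ", x$reason))
  cat(sprintf("Final energy: %.6g\n", x$energy))
  cat(sprintf("Object pixels: %d of %d (%.1f%%)\n",
              sum(x$mask), prod(x$dim), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
summary.fuzzy_ac <- function(object, ...) {
  structure(list(fit = object), class = "summary.fuzzy_ac")
}

#' @export
print.summary.fuzzy_ac <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nParameters:\n")
  p <- f$params
  for (nm in names(p)) cat(sprintf("  %-14s %s\n", nm, format(p[[nm]])))
  tr <- data.frame(iteration = seq_along(f$energy_trace),
                   energy = f$energy_trace,
                   band = f$band_trace,
                   accepted = f$accepted_trace)
  cat("\nTrace (first/last iterations):\n")
  n <- nrow(tr)
  show <- unique(c(seq_len(min(3L, n)), max(1L, n - 2L):n))
  print(tr[show, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Membership map of a fitted contour model
#' @param object a `fuzzy_ac` fit.
#' @param ... unused.
#' @return numeric membership matrix.
#' @export
fitted.fuzzy_ac <- function(object, ...) object$membership

#' Predict the segmentation of a fitted contour model
#'
#' @param object a `fuzzy_ac` fit.
#' @param type `"mask"` for the binary object mask (strict 0.5 level set) or
#'   `"membership"` for the fuzzy map.
#' @param ... unused.
#' @return logical mask or numeric membership matrix.
#' @export
predict.fuzzy_ac <- function(object, type = c("mask", "membership"), ...) {
  type <- match.arg(type)
  if (type == "mask") object$mask else object$membership
}

#' Plot a fitted contour model
#'
#' Displays the segmentation contour (the 0.5 membership level) over either
#' the membership map or a user-supplied image, plus the energy trace.
#'
#' @param x a `fuzzy_ac` fit.
#' @param image optional intensity matrix to use as the backdrop.
#' @param which `"contour"`, `"energy"`, or both.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.fuzzy_ac <- function(x, image = NULL, which = c("contour", "energy"),
                          ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- par(mfrow = c(1, length(which)))
  on.exit(par(op))
  if ("contour" %in% which) {
    bg <- if (is.null(image)) x$membership else image
    # transpose/flip so row 1 is drawn at the top
    disp <- t(bg[nrow(bg):1, , drop = FALSE])
    image(disp, col = gray(seq(0, 1, length.out = 256)), axes = FALSE,
          asp = nrow(bg) / ncol(bg), ...)
    um <- t(x$membership[nrow(x$membership):1, , drop = FALSE])
    contour(um, levels = 0.5, add = TRUE, col = "red", drawlabels = FALSE)
    title(sprintf("%s contour", toupper(x$params$model)))
  }
  if ("energy" %in% which) {
    plot(seq_along(x$energy_trace), x$energy_trace, type = "b", pch = 20,
         xlab = "iteration", ylab = "energy F")
    title("energy trace")
  }
  invisible(x)
}
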