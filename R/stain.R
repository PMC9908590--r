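#' Stain model and Macenko estimation
#'
#' H&E stain mixing is approximately linear in optical density,
#' `OD = -log10((I + 1) / io_white)` per channel. The Macenko estimator
#' projects the OD cloud of tissue pixels onto the plane of its top two
#' singular directions and takes extreme percentile angles within that plane
#' as the two stain directions; hematoxylin is the vector with the larger
#' blue-channel absorbance.
#'
#' @param img RGB array (`h x w x 3`, values 0-255).
#' @param beta OD transparency threshold: pixels with all-channel OD below
#'   `beta` are background and are discarded.
#' @param alpha Robust angle percentile (the stain directions are the
#'   `alpha` and `100 - alpha` percentile angles).
#' @param io_white Transmitted-light white reference intensity.
#' @return A `stain_model`: list with `stain_matrix` (3 x 2, unit columns,
#'   hematoxylin first), `max_concentrations` (length 2, 99th-percentile
#'   reference), and `io_white`.
#' @export
macenko_fit <- function(img, beta = 0.15, alpha = 1, io_white = 255) {
  od <- rgb_to_od(img, io_white)          # n x 3
  keep <- apply(od, 1, max) >= beta       # discard pixels transparent in every channel
  od <- od[keep, , drop = FALSE]
  if (nrow(od) < 100) {
    wsianno_abort("INSUFFICIENT_TISSUE", paste0(
      "only ", nrow(od), " usable (non-background) pixels; at least 100 needed"
    ))
  }
  sv <- svd(od, nu = 0, nv = 3)
  if (sv$d[2] < 1e-8 * sv$d[1]) {
    wsianno_abort("DEGENERATE_STAINS", "optical-density cloud is rank-1 (single stain)")
  }
  basis <- sv$v[, 1:2, drop = FALSE]      # 3 x 2 plane basis
  # orient the basis so projections are positive on average
  for (k in 1:2) if (sum(od %*% basis[, k]) < 0) basis[, k] <- -basis[, k]
  proj <- od %*% basis                    # n x 2
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- quantile(phi, probs = c(alpha / 100, 1 - alpha / 100), names = FALSE)
  if (abs(qs[2] - qs[1]) < 1e-4) {
    wsianno_abort("DEGENERATE_STAINS", "percentile angles collapse (single stain)")
  }
  v1 <- basis %*% rbind(cos(qs[1]), sin(qs[1]))
  v2 <- basis %*% rbind(cos(qs[2]), sin(qs[2]))
  unitize <- function(v) {
    v <- as.numeric(v)
    if (v[which.max(abs(v))] < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  v1 <- unitize(v1); v2 <- unitize(v2)
  # hematoxylin has the larger blue (third channel) absorbance
  m <- if (v1[3] >= v2[3]) cbind(v1, v2) else cbind(v2, v1)
  colnames(m) <- c("hematoxylin", "eosin")
  conc <- od_concentrations(od, m, clip = TRUE)
  max_c <- apply(conc, 2, quantile, probs = 0.99, names = FALSE)
  structure(
    list(stain_matrix = m, max_concentrations = pmax(max_c, 1e-6), io_white = io_white),
    class = "stain_model"
  )
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n")
  print(round(x$stain_matrix, 4))
  cat("max concentrations:", round(x$max_concentrations, 4), "\n")
  invisible(x)
}

rgb_to_od <- function(img, io_white = 255) {
  n <- prod(dim(img)[1:2])
  I <- matrix(img, nrow = n, ncol = 3)
  -log10((I + 1) / io_white)
}

od_to_rgb <- function(od, dims, io_white = 255) {
  I <- io_white * 10^(-od) - 1
  I <- pmin(pmax(I, 0), 255)
  array(I, dim = c(dims, 3))
}

# least-squares stain concentrations (n x 2). Reconstruction keeps the raw
# projection (so normalizing an image to its own model is the identity);
# callers clip when a physical non-negative concentration is needed.
od_concentrations <- function(od, stain_matrix, clip = FALSE) {
  c_hat <- t(qr.solve(stain_matrix, t(od)))
  if (clip) pmax(c_hat, 0) else c_hat
}

#' Normalize an image from a source to a target stain model
#'
#' Decomposes the image into source-stain concentrations, rescales each
#' stain channel by the ratio of target to source reference (99th
#' percentile) concentrations, and recomposes with the target stain matrix.
#' Background stays near-white because its concentrations are near zero.
#'
#' @param img RGB array (0-255).
#' @param source [macenko_fit()] model of the image itself.
#' @param target Reference stain model to map onto.
#' @return RGB array of the same dimensions, values 0-255.
#' @export
macenko_normalize <- function(img, source, target) {
  stopifnot(inherits(source, "stain_model"), inherits(target, "stain_model"))
  dims <- dim(img)[1:2]
  od <- rgb_to_od(img, source$io_white)
  conc <- od_concentrations(od, source$stain_matrix)
  conc <- sweep(conc, 2, target$max_concentrations / source$max_concentrations, `*`)
  od_new <- conc %*% t(target$stain_matrix)
  od_to_rgb(od_new, dims, target$io_white)
}

#' Angle between two stain vectors, in degrees
#'
#' @param a,b Unit 3-vectors.
#' @return Angle in degrees.
#' @export
stain_angle_deg <- function(a, b) {
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}
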