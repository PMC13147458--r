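# Cell-shape descriptors from integer label masks.

# marching-squares perimeter of a binary sub-mask, in pixel units:
# total length of the 0.5-level contour of the label indicator,
# computed on pixel centers (sub-pixel, anti-aliased by linear
# interpolation of the contouring)
contour_perimeter <- function(bin, smooth_window = 3) {
  # pad so the contour closes around border-adjacent shapes
  z <- matrix(0, nrow(bin) + 2, ncol(bin) + 2)
  z[2:(nrow(bin) + 1), 2:(ncol(bin) + 1)] <- bin
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  total <- 0
  for (seg in cl) {
    xs <- seg$x; ys <- seg$y
    closed <- xs[1] == xs[length(xs)] && ys[1] == ys[length(ys)]
    if (closed) { xs <- xs[-length(xs)]; ys <- ys[-length(ys)] }
    n <- length(xs)
    if (smooth_window > 1 && n > smooth_window) {
      # circular moving average de-aliases the pixel staircase, which
      # otherwise biases smooth-boundary perimeters high by ~5%
      k <- floor(smooth_window / 2)
      wrap <- function(v) c(v[(n - k + 1):n], v, v[1:k])
      f <- rep(1 / smooth_window, smooth_window)
      xs <- stats::filter(wrap(xs), f)[(k + 1):(k + n)]
      ys <- stats::filter(wrap(ys), f)[(k + 1):(k + n)]
    }
    xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
    total <- total + sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }
  total
}

#' Cell-shape descriptors from a label mask
#'
#' Per-cell morphometrics: area (pixel count times pixel area),
#' perimeter (sub-pixel marching-squares contour length), length and
#' width (ellipse-equivalent major and minor axes from second moments),
#' aspect ratio (length/width) and circularity
#' (`4 * pi * area / perimeter^2`). Cells touching the image border are
#' excluded (count reported in attribute `n_border_excluded`);
#' single-pixel labels are excluded with a warning.
#'
#' @param mask A [label_mask()] with known `pixel_size`.
#' @return `data.frame`: `label`, `area_um2`, `perimeter_um`,
#'   `length_um`, `width_um`, `aspect_ratio`, `circularity`.
#' @export
shape_descriptors <- function(mask) {
  ps_um <- attr(mask, "pixel_size") / 1000
  labs <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (!length(labs)) abort_input("mask contains no labelled cells")
  nr <- nrow(mask); nc <- ncol(mask)
  n_border <- 0L; n_tiny <- 0L
  rows <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    l <- labs[i]
    idx <- which(mask == l)
    r <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    if (any(r == 1L | r == nr | cc == 1L | cc == nc)) {
      n_border <- n_border + 1L
      next
    }
    if (length(idx) < 2L) {
      n_tiny <- n_tiny + 1L
      next
    }
    area <- length(idx) * ps_um^2
    # bounding box with one-pixel pad for the contour
    r0 <- min(r) - 1L; c0 <- min(cc) - 1L
    bin <- matrix(0, max(r) - r0 + 2L, max(cc) - c0 + 2L)
    bin[cbind(r - r0 + 1L, cc - c0 + 1L)] <- 1
    perim <- contour_perimeter(bin) * ps_um
    # ellipse-equivalent axes from central second moments
    # (+1/12: uniform spread of mass within each pixel)
    mr <- r - mean(r); mc <- cc - mean(cc)
    cxx <- mean(mc^2) + 1 / 12
    cyy <- mean(mr^2) + 1 / 12
    cxy <- mean(mr * mc)
    tr <- cxx + cyy
    det_ <- cxx * cyy - cxy^2
    l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det_, 0))
    l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det_, 0))
    len <- 4 * sqrt(l1) * ps_um
    wid <- 4 * sqrt(max(l2, 0)) * ps_um
    rows[[i]] <- data.frame(label = l, area_um2 = area,
                            perimeter_um = perim,
                            length_um = len, width_um = wid,
                            aspect_ratio = len / wid,
                            circularity = 4 * pi * area / perim^2)
  }
  if (n_tiny > 0)
    warning(sprintf("%d single-pixel label(s) excluded", n_tiny))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), length_um = numeric(),
                      width_um = numeric(), aspect_ratio = numeric(),
                      circularity = numeric())
  rownames(out) <- NULL
  attr(out, "n_border_excluded") <- n_border
  out
}

#' Rank comparison of shape-descriptor distributions
#'
#' Mann-Whitney U test between one descriptor column of two cell
#' populations (thin wrapper over [mann_whitney_u()] with unit
#' weights).
#'
#' @param group_a,group_b Numeric descriptor vectors.
#' @return List with `U_a`, `U_b`, `p_value`, `n_a`, `n_b`.
#' @export
rank_compare_shapes <- function(group_a, group_b) {
  mann_whitney_u(group_a, group_b)
}
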