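#' Binarize a grayscale image
#'
#' Default method is Otsu's threshold (maximizing between-class variance,
#' via [EBImage::otsu()]); a fixed absolute threshold is also available. A
#' constant image yields an empty mask with a warning and the `flagged`
#' attribute set, not an error.
#'
#' @param image A [labeled_image].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Absolute intensity cutoff for `method = "fixed"`.
#' @return Logical matrix mask (TRUE = foreground) with attributes
#'   `px_size_um` and `flagged`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(image, "labeled_image"))
  method <- match.arg(method)
  px <- image$pixels
  rng <- range(px)
  flagged <- FALSE
  if (rng[2] - rng[1] <= 0) {
    rlang::warn("constant image: empty mask returned", class = "tg_flat_image")
    mask <- matrix(FALSE, nrow(px), ncol(px))
    flagged <- TRUE
  } else if (method == "fixed") {
    if (is.null(threshold))
      tg_stop("fixed thresholding needs `threshold`", "tg_parameter_error")
    mask <- px > threshold
  } else {
    scaled <- (px - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    mask <- scaled > th
  }
  attr(mask, "px_size_um") <- image$px_size_um
  attr(mask, "flagged") <- flagged
  mask
}

# shift a logical matrix by (dy, dx), padding with FALSE
tg_shift <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

# the eight neighbours in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
tg_zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                      c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Parallel Zhang-Suen thinning to a 1-pixel skeleton, then graph extraction
#' with 8-connectivity following AnalyzeSkeleton conventions: endpoints are
#' skeleton pixels with exactly one neighbour, junction pixels have three or
#' more, and 8-adjacent junction pixels are merged into single junction
#' nodes. Branches are the connected components of the skeleton with
#' junction pixels removed; branch length sums pixel steps (1 per axial,
#' sqrt(2) per diagonal adjacency) times the pixel size, so a 50-pixel line
#' at 1 um/px has length 49 um.
#'
#' @param mask Logical matrix (e.g. from [binarize()]).
#' @param px_size_um Micrometres per pixel (default: the mask's
#'   `px_size_um` attribute, else 1).
#' @return A `skeleton_graph` list: `skeleton` (logical matrix),
#'   `n_endpoints`, `n_junctions`, `n_branches`, `n_isolated`,
#'   `total_length_um`, `branch_lengths_um`.
#' @export
skeletonize <- function(mask, px_size_um = NULL) {
  px_size_um <- px_size_um %||% attr(mask, "px_size_um") %||% 1
  m <- mask
  storage.mode(m) <- "logical"
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- lapply(tg_zs_offsets, function(o) tg_shift(m, o[1], o[2]))
      B <- Reduce(`+`, nb)
      seqs <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(i)
        (!seqs[[i]]) & seqs[[i + 1]]))
      if (pass == 1) {
        c3 <- !(nb[[1]] & nb[[3]] & nb[[5]])   # P2 P4 P6
        c4 <- !(nb[[3]] & nb[[5]] & nb[[7]])   # P4 P6 P8
      } else {
        c3 <- !(nb[[1]] & nb[[3]] & nb[[7]])   # P2 P4 P8
        c4 <- !(nb[[1]] & nb[[5]] & nb[[7]])   # P2 P6 P8
      }
      del <- m & (B >= 2) & (B <= 6) & (A == 1) & c3 & c4
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  nb <- lapply(tg_zs_offsets, function(o) tg_shift(m, o[1], o[2]))
  B <- Reduce(`+`, nb)
  endpoints <- m & (B == 1)
  isolated <- m & (B == 0)
  junction_px <- m & (B >= 3)
  n_junctions <- if (any(junction_px))
    max(tg_label8(junction_px)) else 0L

  body <- m & !junction_px
  lab <- tg_label8(body)
  n_branches <- max(lab, 0)
  branch_lengths <- numeric(0)
  if (n_branches > 0) {
    lens <- numeric(n_branches)
    for (o in list(c(0, 1), c(1, 0))) {          # axial pairs, counted once
      sh <- tg_shift_num(lab, o[1], o[2])
      sel <- lab > 0 & sh == lab
      if (any(sel)) lens <- lens + tabulate(lab[sel], nbins = n_branches)
    }
    diag_cnt <- numeric(n_branches)
    for (o in list(c(1, 1), c(1, -1))) {         # diagonal pairs
      sh <- tg_shift_num(lab, o[1], o[2])
      sel <- lab > 0 & sh == lab
      if (any(sel)) diag_cnt <- diag_cnt + tabulate(lab[sel], nbins = n_branches)
    }
    branch_lengths <- (lens + sqrt(2) * diag_cnt) * px_size_um
  }

  structure(list(
    skeleton = m,
    n_endpoints = sum(endpoints),
    n_junctions = as.integer(n_junctions),
    n_branches = as.integer(n_branches),
    n_isolated = sum(isolated),
    total_length_um = sum(branch_lengths),
    branch_lengths_um = branch_lengths,
    px_size_um = px_size_um
  ), class = "skeleton_graph")
}

# 8-connected component labelling of a logical mask; returns an integer
# matrix (0 = background, components numbered 1..n). EBImage::bwlabel is
# 4-connected, which would split diagonal skeleton runs, hence this one.
tg_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  rank <- integer(length(mask))
  rank[idx] <- seq_along(idx)
  H <- nrow(mask)
  edges <- list()
  # forward neighbours only: E, S, SE, NE (each unordered pair once)
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
    sh <- tg_shift(mask, o[1], o[2])
    both <- which(mask & sh)
    if (length(both)) {
      nb_idx <- both + o[1] + o[2] * H
      edges[[length(edges) + 1]] <- cbind(rank[both], rank[nb_idx])
    }
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  lab[idx] <- igraph::components(g)$membership[seq_along(idx)]
  lab
}

# numeric-matrix shift with 0 padding (for label matrices)
tg_shift_num <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d endpoints, %d junctions, %d branches, %.1f um total\n",
    x$n_endpoints, x$n_junctions, x$n_branches, x$total_length_um))
  invisible(x)
}

#' Soma diameters from a binary mask
#'
#' Somas are found as the cores of the Euclidean distance transform: pixels
#' whose distance to background reaches the radius of the minimum acceptable
#' inscribed disk (`min_soma_area_um2`) form soma cores; each core is one
#' cell, and its diameter is twice the core's maximal distance, less half a
#' pixel of raster bias (the transform measures to the centre of the first
#' background pixel). Thin processes never reach the core radius, so a
#' soma with attached processes keeps its diameter, and touching processes
#' do not merge cells.
#'
#' @param mask Logical matrix.
#' @param px_size_um Micrometres per pixel (default: mask attribute, else 1).
#' @param min_soma_area_um2 Minimum inscribed-disk area for a region to count
#'   as a soma rather than a process fragment (default 12 um^2).
#' @return Tibble with one row per detected soma: `soma`, `x_px`, `y_px`,
#'   `diameter_um`.
#' @export
soma_diameter <- function(mask, px_size_um = NULL, min_soma_area_um2 = 12) {
  px_size_um <- px_size_um %||% attr(mask, "px_size_um") %||% 1
  empty <- tibble::tibble(soma = integer(), x_px = numeric(),
                          y_px = numeric(), diameter_um = numeric())
  if (!any(mask)) return(empty)
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  r_min_px <- sqrt(min_soma_area_um2 / pi) / px_size_um
  core <- dm >= r_min_px
  if (!any(core)) return(empty)
  lab <- tg_label8(core)
  n <- max(lab)
  purrr::map_dfr(seq_len(n), function(i) {
    sel <- which(lab == i, arr.ind = TRUE)
    d <- dm[lab == i]
    best <- which.max(d)
    tibble::tibble(soma = i, x_px = sel[best, 2], y_px = sel[best, 1],
                   diameter_um = (2 * max(d) - 0.5) * px_size_um)
  })
}

#' Full morphometry of one stained field
#'
#' Composition of [binarize()], [skeletonize()] and [soma_diameter()]:
#' per-field cell count, branch/junction/endpoint totals (and per-cell
#' means), total process length, mean soma diameter and stained-area
#' fraction. For a plaque (`"abeta"`) channel only the area fraction is
#' meaningful; skeleton counts are still reported.
#'
#' @param image A [labeled_image].
#' @param min_soma_area_um2 Passed to [soma_diameter()].
#' @param method,threshold Passed to [binarize()].
#' @return One-row tibble: `channel`, `n_cells`, `n_branches`,
#'   `n_junctions`, `n_endpoints`, `total_length_um`, per-cell means,
#'   `mean_soma_diameter_um`, `area_fraction`, `field_area_um2`, `flagged`.
#' @export
field_metrics <- function(image, min_soma_area_um2 = 12,
                          method = "otsu", threshold = NULL) {
  stopifnot(inherits(image, "labeled_image"))
  mask <- binarize(image, method = method, threshold = threshold)
  sk <- skeletonize(mask, px_size_um = image$px_size_um)
  somas <- soma_diameter(mask, px_size_um = image$px_size_um,
                         min_soma_area_um2 = min_soma_area_um2)
  n_cells <- nrow(somas)
  per_cell <- function(x) if (n_cells > 0) x / n_cells else NA_real_
  tibble::tibble(
    channel = image$channel,
    n_cells = n_cells,
    n_branches = sk$n_branches,
    n_junctions = sk$n_junctions,
    n_endpoints = sk$n_endpoints,
    total_length_um = sk$total_length_um,
    branches_per_cell = per_cell(sk$n_branches),
    endpoints_per_cell = per_cell(sk$n_endpoints),
    length_per_cell_um = per_cell(sk$total_length_um),
    mean_soma_diameter_um = if (n_cells > 0) mean(somas$diameter_um)
                            else NA_real_,
    area_fraction = mean(mask),
    field_area_um2 = nrow(image$pixels) * ncol(image$pixels) *
      image$px_size_um^2,
    flagged = isTRUE(attr(mask, "flagged"))
  )
}
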