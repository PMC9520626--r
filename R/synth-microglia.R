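#' Parameters for a synthetic microglia field
#'
#' Emulates an Iba1-stained hippocampal field: bright somas (disks) with
#' radiating, optionally bifurcating processes drawn as 1-pixel polylines on
#' the 8-connected lattice, on a dark background. Because processes run along
#' lattice directions (multiples of 45 degrees) and cells are placed with
#' enough clearance never to touch, the drawn tree IS its own topological
#' skeleton: thinning a noiseless skeletal render leaves it unchanged, so the
#' ground-truth endpoint/junction counts are exact by construction. With a
#' filled soma (`render_soma = TRUE`) the thinned soma blob can contribute a
#' small number of extra hub pixels, so full-render topology is recovered
#' approximately rather than exactly.
#'
#' @param field_um Field size `c(width, height)` in micrometres (default
#'   `c(800, 300)`, one counting region).
#' @param px_per_um Pixels per micrometre (default 1).
#' @param n_cells Number of cells (default 10).
#' @param soma_diameter_um Mean and SD of soma diameter, um (default
#'   `c(7, 0.8)`; activated microglia have larger somas).
#' @param processes_per_cell Primary processes per cell, 1-8 (default 4;
#'   directions are spread evenly around the soma).
#' @param process_length_um Mean and SD of process length, um (default
#'   `c(25, 5)`).
#' @param branching_prob Probability a process bifurcates at its midpoint
#'   (default 0.3).
#' @param render_soma Draw the filled soma disk (default TRUE). `FALSE`
#'   renders only the process tree rooted at the soma centre - the skeletal
#'   render used for exact topology checks.
#' @param blur_sigma_um Gaussian blur SD in um (default 0 = noiseless).
#' @param noise_sd Additive Gaussian intensity noise SD, on a foreground
#'   intensity of 1 (default 0).
#' @param seed RNG seed.
#' @return A validated `microglia_scene_params` list.
#' @export
microglia_scene_params <- function(field_um = c(800, 300), px_per_um = 1,
                                   n_cells = 10,
                                   soma_diameter_um = c(7, 0.8),
                                   processes_per_cell = 4,
                                   process_length_um = c(25, 5),
                                   branching_prob = 0.3,
                                   render_soma = TRUE,
                                   blur_sigma_um = 0, noise_sd = 0,
                                   seed = 1) {
  if (n_cells < 0) tg_stop("`n_cells` must be >= 0", "tg_parameter_error")
  if (soma_diameter_um[1] <= 0)
    tg_stop("`soma_diameter_um` mean must be positive", "tg_parameter_error")
  if (!(branching_prob >= 0 && branching_prob <= 1))
    tg_stop("`branching_prob` must lie in [0, 1]", "tg_parameter_error")
  if (!(processes_per_cell >= 1 && processes_per_cell <= 8))
    tg_stop("`processes_per_cell` must be 1-8", "tg_parameter_error")
  if (length(soma_diameter_um) == 1) soma_diameter_um <- c(soma_diameter_um, 0)
  if (length(process_length_um) == 1) process_length_um <- c(process_length_um, 0)
  structure(list(field_um = field_um, px_per_um = px_per_um,
                 n_cells = as.integer(n_cells),
                 soma_diameter_um = soma_diameter_um,
                 processes_per_cell = as.integer(processes_per_cell),
                 process_length_um = process_length_um,
                 branching_prob = branching_prob,
                 render_soma = isTRUE(render_soma),
                 blur_sigma_um = blur_sigma_um, noise_sd = noise_sd,
                 seed = seed),
            class = "microglia_scene_params")
}

# the 8 lattice directions, clockwise from east; step length 1 or sqrt(2)
tg_dirs <- matrix(c(1, 0, 1, 1, 0, 1, -1, 1, -1, 0, -1, -1, 0, -1, 1, -1),
                  ncol = 2, byrow = TRUE)
tg_step_len <- sqrt(rowSums(tg_dirs^2))

# walk `len` pixels from (x0, y0) in direction index d (1-8), marking mask;
# returns list(mask, tip = last pixel, length_px = path length in px units,
# pixels = two-column matrix of visited pixels)
tg_walk <- function(mask, x0, y0, d, len) {
  W <- ncol(mask); H <- nrow(mask)
  dx <- tg_dirs[d, 1]; dy <- tg_dirs[d, 2]
  x <- x0; y <- y0; plen <- 0; tip <- c(x0, y0)
  for (i in seq_len(len)) {
    x <- x + dx; y <- y + dy
    if (x < 1 || x > W || y < 1 || y > H) break
    mask[y, x] <- TRUE
    plen <- plen + tg_step_len[d]
    tip <- c(x, y)
  }
  list(mask = mask, tip = tip, length_px = plen)
}

#' Generate a synthetic microglia image with ground truth
#'
#' Deterministic given the seed. Cells are placed by rejection sampling with
#' a clearance radius covering the soma plus the longest possible process, so
#' cells never touch; if placement fails after bounded retries a generation
#' error is raised.
#'
#' @param params A [microglia_scene_params()].
#' @return A list:
#' \describe{
#'   \item{image}{A [labeled_image] (channel `"iba1"`).}
#'   \item{mask}{The noiseless logical foreground mask actually drawn.}
#'   \item{ground_truth}{List with per-cell tibble `cells` (position, soma
#'     diameter, tips, bifurcations, expected skeleton endpoints/junctions,
#'     process length) and element `totals`.}
#' }
#' @export
generate_microglia_image <- function(params) {
  stopifnot(inherits(params, "microglia_scene_params"))
  ppu <- params$px_per_um
  W <- round(params$field_um[1] * ppu)
  H <- round(params$field_um[2] * ppu)
  mask <- matrix(FALSE, H, W)
  soma_mask <- matrix(FALSE, H, W)
  n <- params$n_cells
  empty_gt <- tibble::tibble(cell = integer(), x_um = numeric(),
                             y_um = numeric(), soma_diameter_um = numeric(),
                             n_processes = integer(), n_tips = integer(),
                             n_bifurcations = integer(),
                             gt_endpoints = integer(), gt_junctions = integer(),
                             process_length_um = numeric())
  if (n == 0) {
    img <- labeled_image(mask * 1, px_size_um = 1 / ppu, channel = "iba1")
    return(list(image = img, mask = mask,
                ground_truth = list(cells = empty_gt,
                                    totals = tg_gt_totals(empty_gt))))
  }

  res <- withr::with_seed(params$seed, {
    dmu <- params$soma_diameter_um; lmu <- params$process_length_um
    k <- params$processes_per_cell
    # sample every cell's geometry up front so placement can use each
    # cell's actual spatial reach rather than a worst-case bound
    geom <- lapply(seq_len(n), function(ci) {
      offset <- sample.int(8, 1) - 1L
      list(d_um = max(2, stats::rnorm(1, dmu[1], dmu[2])),
           dirs = (offset + round((seq_len(k) - 1) * 8 / k)) %% 8L + 1L,
           L_um = pmax(4, stats::rnorm(k, lmu[1], lmu[2])),
           branch = stats::runif(k) < params$branching_prob)
    })
    reach_px <- vapply(geom, function(g)
      (g$d_um / 2 + max(g$L_um) + 2) * ppu, 0)
    if (n >= 1 && 2 * max(reach_px) >= min(W, H))
      tg_stop("field too small for one cell with its processes",
              "tg_generation_error")
    # placing the largest-reach cells first raises the packing ceiling
    geom <- geom[order(-reach_px)]
    reach_px <- sort(reach_px, decreasing = TRUE)
    centers <- matrix(NA_real_, n, 2)
    placed <- 0L; tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 300L * n)
        tg_stop(sprintf("cannot place %d non-overlapping cells in the field",
                        n), "tg_generation_error")
      ci <- placed + 1L
      cx <- stats::runif(1, reach_px[ci] + 1, W - reach_px[ci])
      cy <- stats::runif(1, reach_px[ci] + 1, H - reach_px[ci])
      if (placed > 0) {
        dd <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                     (centers[seq_len(placed), 2] - cy)^2)
        if (any(dd < reach_px[seq_len(placed)] + reach_px[ci])) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy)
    }

    cells <- vector("list", n)
    for (ci in seq_len(n)) {
      cx <- round(centers[ci, 1]); cy <- round(centers[ci, 2])
      mask[cy, cx] <- TRUE   # root pixel: keeps diagonal arms connected
      d_um <- geom[[ci]]$d_um
      r_px <- d_um * ppu / 2
      dirs <- geom[[ci]]$dirs
      n_tips <- 0L; n_bif <- 0L; plen_um <- 0
      for (pi_ in seq_along(dirs)) {
        d <- dirs[pi_]
        L_um <- geom[[ci]]$L_um[pi_]
        L_px <- max(3L, round(L_um * ppu / tg_step_len[d]))
        r_steps <- ceiling(r_px / tg_step_len[d])
        branch <- geom[[ci]]$branch[pi_]
        if (!branch) {
          wk <- tg_walk(mask, cx, cy, d, r_steps + L_px)
          mask <- wk$mask
          n_tips <- n_tips + 1L
          plen_um <- plen_um + max(0, wk$length_px - r_steps * tg_step_len[d]) / ppu
        } else {
          half <- L_px %/% 2L
          wk <- tg_walk(mask, cx, cy, d, r_steps + half)
          mask <- wk$mask
          n_bif <- n_bif + 1L
          plen_um <- plen_um + max(0, wk$length_px - r_steps * tg_step_len[d]) / ppu
          for (dd in c((d - 2L) %% 8L + 1L, d %% 8L + 1L)) {
            wk2 <- tg_walk(mask, wk$tip[1], wk$tip[2], dd, max(3L, half))
            mask <- wk2$mask
            n_tips <- n_tips + 1L
            plen_um <- plen_um + wk2$length_px / ppu
          }
        }
      }
      if (params$render_soma) {
        xr <- pmax(1, cx - ceiling(r_px)):pmin(W, cx + ceiling(r_px))
        yr <- pmax(1, cy - ceiling(r_px)):pmin(H, cy + ceiling(r_px))
        dist2 <- outer((yr - cy)^2, (xr - cx)^2, "+")
        soma_mask[yr, xr] <- soma_mask[yr, xr] | (dist2 <= r_px^2)
      }
      cells[[ci]] <- tibble::tibble(
        cell = ci, x_um = cx / ppu, y_um = cy / ppu,
        soma_diameter_um = d_um, n_processes = k,
        n_tips = n_tips, n_bifurcations = n_bif,
        gt_endpoints = n_tips + as.integer(k == 1L),
        gt_junctions = n_bif + as.integer(k >= 3L),
        process_length_um = plen_um)
    }
    list(mask = mask | soma_mask, cells = dplyr::bind_rows(cells))
  })

  mask <- res$mask
  px <- mask * 1.0
  if (params$blur_sigma_um > 0)
    px <- as.matrix(EBImage::gblur(px, sigma = params$blur_sigma_um * ppu))
  if (params$noise_sd > 0)
    px <- px + withr::with_seed(params$seed + 1L,
                                matrix(stats::rnorm(length(px), 0,
                                                    params$noise_sd), H, W))
  px <- pmax(px, 0)
  img <- labeled_image(px, px_size_um = 1 / ppu, channel = "iba1")
  list(image = img, mask = mask,
       ground_truth = list(cells = res$cells,
                           totals = tg_gt_totals(res$cells)))
}

tg_gt_totals <- function(cells) {
  list(n_cells = nrow(cells),
       endpoints = sum(cells$gt_endpoints),
       junctions = sum(cells$gt_junctions),
       process_length_um = sum(cells$process_length_um))
}

#' Generate a synthetic amyloid-plaque image
#'
#' Round plaques of lognormal-ish size on a dark background; ground truth
#' carries the exact drawn foreground area fraction.
#'
#' @param field_um Field size `c(width, height)` in um (default `c(800, 300)`).
#' @param px_per_um Pixels per um (default 1).
#' @param n_plaques Number of plaques (default 12).
#' @param plaque_diameter_um Mean and SD of plaque diameter, um
#'   (default `c(15, 5)`).
#' @param seed RNG seed.
#' @return List with `image` (a [labeled_image], channel `"abeta"`) and
#'   `ground_truth` (list with `area_fraction`).
#' @export
generate_plaque_image <- function(field_um = c(800, 300), px_per_um = 1,
                                  n_plaques = 12,
                                  plaque_diameter_um = c(15, 5), seed = 1) {
  W <- round(field_um[1] * px_per_um); H <- round(field_um[2] * px_per_um)
  mask <- withr::with_seed(seed, {
    m <- matrix(FALSE, H, W)
    for (i in seq_len(n_plaques)) {
      d <- max(3, stats::rnorm(1, plaque_diameter_um[1], plaque_diameter_um[2]))
      r <- d * px_per_um / 2
      cx <- stats::runif(1, r + 1, W - r); cy <- stats::runif(1, r + 1, H - r)
      xr <- floor(cx - r):ceiling(cx + r); yr <- floor(cy - r):ceiling(cy + r)
      xr <- xr[xr >= 1 & xr <= W]; yr <- yr[yr >= 1 & yr <= H]
      m[yr, xr] <- m[yr, xr] | (outer((yr - cy)^2, (xr - cx)^2, "+") <= r^2)
    }
    m
  })
  img <- labeled_image(mask * 1.0, px_size_um = 1 / px_per_um,
                       channel = "abeta")
  list(image = img,
       ground_truth = list(area_fraction = mean(mask)))
}
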