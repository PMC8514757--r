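# Synthetic infarct substrate generator: 2D myocardial sheet with scar,
# border zone, conducting channels, a fiber-angle field, and pacing sites.
# Emulates the statistical structure of patient infarct distributions
# (anterior/apical scar localization, scar ~12.6% and border zone ~6.8% of
# myocardium) on a rectangular sheet: axis 0 (rows) runs base -> apex,
# axis 1 (columns) runs endocardium -> epicardium.

TISSUE_LEVELS <- c(normal = 0L, border_zone = 1L, scar = 2L, outside = 3L)

#' Substrate generator parameters
#'
#' @param nr,nc Grid dimensions (nodes); rows = apicobasal axis (row 1 =
#'   base), columns = transmural/lateral axis.
#' @param dx Node spacing (mm).
#' @param target_scar_fraction Target scar node fraction of myocardium.
#' @param target_bz_fraction Target border-zone node fraction.
#' @param n_channels Number of conducting channels carved through the scar.
#' @param channel_min_width Minimum channel width (mm).
#' @param scar_centroid_ab Normalized apicobasal position of the scar
#'   centroid in `[0,1]` (0 = base, 1 = apex); default apical.
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @param geometry Only `"sheet2d"` is implemented; `"slab3d"` errors.
#' @param smooth_sigma Gaussian smoothing length of the scar-shape noise
#'   (nodes); default `min(nr, nc) / 16`.
#' @param loc_sigma Width (normalized units) of the localization envelope.
#' @param noise_amp Log-amplitude of the shape noise.
#' @param fiber_span Total transmural fiber rotation (radians); the fiber
#'   angle varies linearly from `-fiber_span/2` at the endocardial edge to
#'   `+fiber_span/2` at the epicardial edge.
#' @param n_pacing_sites Number of pacing sites (>= 3) near the apical edge
#'   ("RV-apex analog"), pairwise at least `pacing_min_dist` mm apart.
#' @param pacing_min_dist Minimum pacing-site separation (mm).
#' @param max_retries Rejection-resampling cap for hitting the fraction
#'   targets within 20% relative.
#' @return Object of class `substrate_params`.
#' @export
substrate_params <- function(nr = 192, nc = 192, dx = 0.25,
                             target_scar_fraction = 0.126,
                             target_bz_fraction = 0.068,
                             n_channels = 1, channel_min_width = 1.0,
                             scar_centroid_ab = 0.75, rng_seed = 1L,
                             geometry = c("sheet2d", "slab3d"),
                             smooth_sigma = NULL, loc_sigma = 0.16,
                             noise_amp = 0.9,
                             fiber_span = 2 * pi / 3,
                             n_pacing_sites = 3, pacing_min_dist = 5,
                             max_retries = 20) {
  geometry <- match.arg(geometry)
  if (geometry == "slab3d")
    stop("slab3d geometry is not implemented; use sheet2d")
  stopifnot(target_scar_fraction >= 0, target_bz_fraction >= 0,
            target_scar_fraction + target_bz_fraction < 1,
            n_channels >= 0, n_pacing_sites >= 3, dx > 0)
  if (is.null(smooth_sigma)) smooth_sigma <- min(nr, nc) / 16
  structure(list(nr = nr, nc = nc, dx = dx,
                 target_scar_fraction = target_scar_fraction,
                 target_bz_fraction = target_bz_fraction,
                 n_channels = n_channels,
                 channel_min_width = channel_min_width,
                 scar_centroid_ab = scar_centroid_ab,
                 rng_seed = as.integer(rng_seed), geometry = geometry,
                 smooth_sigma = smooth_sigma, loc_sigma = loc_sigma,
                 noise_amp = noise_amp, fiber_span = fiber_span,
                 n_pacing_sites = n_pacing_sites,
                 pacing_min_dist = pacing_min_dist,
                 max_retries = max_retries),
            class = "substrate_params")
}

# periodic Gaussian smoothing via FFT
gauss_smooth <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  r <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  c_ <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  k <- exp(-outer(r^2, c_^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (nr * nc)
}

carve_channel <- function(scar, k, params) {
  nr <- nrow(scar); nc <- ncol(scar)
  rows <- which(rowSums(scar) > 0); cols <- which(colSums(scar) > 0)
  if (!length(rows)) return(scar * FALSE)
  cen_c <- sum(col(scar)[scar]) / sum(scar)
  wid_c <- max(diff(range(cols)), 1)
  off <- runif(1, -0.3, 0.3) * wid_c
  amp <- runif(1, 0, 0.12) * wid_c
  ph <- runif(1, 0, 2 * pi)
  r0 <- max(min(rows) - 2, 1); r1 <- min(max(rows) + 2, nr)
  half_w <- max(params$channel_min_width / params$dx, 2) / 2
  path_c <- cen_c + off + amp * sin(ph + 2 * pi * (r0:r1 - r0) / (r1 - r0 + 1))
  ch <- matrix(FALSE, nr, nc)
  for (i in seq_along(r0:r1)) {
    r <- (r0:r1)[i]
    cc <- seq(max(1, floor(path_c[i] - half_w)),
              min(nc, ceiling(path_c[i] + half_w)))
    ch[r, cc] <- TRUE
  }
  ch & scar
}

#' Generate a synthetic infarct substrate
#'
#' Scar is built by thresholding a smoothed random field modulated by a
#' localization envelope centered at `scar_centroid_ab` on the apicobasal
#' axis, so the achieved scar fraction matches the target by construction;
#' conducting channels are carved through the scar (filled with border-zone
#' tissue) and the border zone is a morphological rim grown around the scar
#' to the target fraction. Generation is deterministic for a fixed seed and
#' resamples (up to `max_retries`) until both achieved fractions are within
#' 20% relative of their targets.
#'
#' @param params A [substrate_params()] object.
#' @return Object of class `tissue_domain`: `tissue_class` (integer matrix,
#'   0 normal / 1 border zone / 2 scar / 3 outside), `fiber_angle` (radians,
#'   matrix), `dx` (mm), `pacing_sites` (matrix of 1-based `(row, col)`;
#'   serialized 0-based), and the generating `params`.
#' @export
generate_substrate <- function(params = substrate_params()) {
  stopifnot(inherits(params, "substrate_params"))
  nr <- params$nr; nc <- params$nc
  half_w <- max(params$channel_min_width / params$dx, 2)
  if (params$n_channels > 0 && (nr < 4 * half_w || nc < 4 * half_w))
    stop("grid too small to fit a channel of channel_min_width")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$rng_seed)

  n_myo <- nr * nc
  target_scar_n <- round(params$target_scar_fraction * n_myo)
  target_bz_n <- round(params$target_bz_fraction * n_myo)

  rn <- (row(matrix(0, nr, nc)) - 1) / (nr - 1)
  cn <- (col(matrix(0, nr, nc)) - 1) / (nc - 1)
  envelope <- exp(-((rn - params$scar_centroid_ab)^2 + (cn - 0.5)^2) /
                    (2 * params$loc_sigma^2))

  for (attempt in seq_len(params$max_retries)) {
    noise <- gauss_smooth(matrix(rnorm(n_myo), nr, nc), params$smooth_sigma)
    noise <- noise / stats::sd(noise)
    score <- envelope * exp(params$noise_amp * noise)
    scar <- matrix(FALSE, nr, nc)
    if (target_scar_n > 0) {
      thr <- sort(score, decreasing = TRUE)[target_scar_n]
      scar <- score >= thr
    }
    # conducting channels through the scar, filled with border-zone tissue;
    # the scar is re-thresholded outside the channel so the carve does not
    # eat into the target scar fraction
    channel <- matrix(FALSE, nr, nc)
    if (params$n_channels > 0 && any(scar)) {
      for (k in seq_len(params$n_channels))
        channel <- channel | carve_channel(scar, k, params)
      score2 <- score
      score2[channel] <- -Inf
      thr <- sort(score2, decreasing = TRUE)[target_scar_n]
      scar <- score2 >= thr
    }
    # border-zone rim grown around the scar
    bz <- channel
    need <- target_bz_n - sum(bz)
    if (need > 0 && any(scar)) {
      prev_rim <- matrix(FALSE, nr, nc)
      for (r in seq_len(max(nr, nc))) {
        rim <- cpp_dilate_disc(scar, r) & !scar & !bz
        if (sum(rim) >= need || r == max(nr, nc)) {
          inner <- prev_rim
          ring <- rim & !inner
          take <- need - sum(inner)
          sel <- which(ring)
          if (take < length(sel)) sel <- sample(sel, take)
          bz[inner] <- TRUE
          bz[sel] <- TRUE
          break
        }
        prev_rim <- rim
      }
    } else if (need > 0) {
      # no scar: scatter a compact border-zone patch at the envelope peak
      thr <- sort(envelope[!bz], decreasing = TRUE)[need]
      bz <- bz | (envelope >= thr & !scar)
    }
    fixed <- absorb_bz_pockets(scar, bz)
    scar <- fixed$scar; bz <- fixed$bz
    got_scar <- sum(scar) / n_myo
    got_bz <- sum(bz) / n_myo
    ok_scar <- params$target_scar_fraction == 0 ||
      abs(got_scar - params$target_scar_fraction) <=
        0.2 * params$target_scar_fraction
    ok_bz <- params$target_bz_fraction == 0 ||
      abs(got_bz - params$target_bz_fraction) <=
        0.2 * params$target_bz_fraction
    if (ok_scar && ok_bz) {
      tc <- matrix(TISSUE_LEVELS[["normal"]], nr, nc)
      tc[bz] <- TISSUE_LEVELS[["border_zone"]]
      tc[scar] <- TISSUE_LEVELS[["scar"]]
      fiber <- matrix(rep(params$fiber_span * ((seq_len(nc) - 1) / (nc - 1) - 0.5),
                          each = nr), nr, nc)
      dom <- structure(list(tissue_class = tc, fiber_angle = fiber,
                            dx = params$dx, params = params,
                            pacing_sites = NULL),
                       class = "tissue_domain")
      dom$pacing_sites <- place_pacing_sites(dom, params$n_pacing_sites,
                                             params$pacing_min_dist)
      return(dom)
    }
  }
  stop(sprintf(
    "generation failure after %d retries: achieved scar %.3f (target %.3f), bz %.3f (target %.3f)",
    params$max_retries, got_scar, params$target_scar_fraction, got_bz,
    params$target_bz_fraction))
}

# deterministic pacing sites on the apical band, snapped off scar
place_pacing_sites <- function(domain, n_sites, min_dist_mm) {
  tc <- domain$tissue_class
  nr <- nrow(tc); nc <- ncol(tc)
  band0 <- max(1, floor(0.92 * nr))
  cols <- round(nc * seq(0.2, 0.8, length.out = n_sites))
  sites <- matrix(NA_integer_, n_sites, 2,
                  dimnames = list(NULL, c("row", "col")))
  conducting <- tc == TISSUE_LEVELS[["normal"]] |
    tc == TISSUE_LEVELS[["border_zone"]]
  cand <- which(conducting & row(tc) >= band0, arr.ind = TRUE)
  if (nrow(cand) < n_sites)
    stop("configuration error: not enough conducting apical nodes for pacing sites")
  for (i in seq_len(n_sites)) {
    d2 <- (cand[, 1] - nr)^2 + (cand[, 2] - cols[i])^2
    ord <- order(d2)
    placed <- FALSE
    for (k in ord) {
      p <- cand[k, ]
      if (i == 1 || all(sqrt((sites[seq_len(i - 1), 1] - p[1])^2 +
                             (sites[seq_len(i - 1), 2] - p[2])^2) *
                          domain$dx >= min_dist_mm)) {
        sites[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (min_dist_mm > 1) {
        warning(sprintf(
          "grid too small for %g mm pacing-site spacing; retrying at %g mm",
          min_dist_mm, min_dist_mm / 2))
        return(place_pacing_sites(domain, n_sites, min_dist_mm / 2))
      }
      stop("configuration error: cannot place pacing sites >= min_dist apart")
    }
  }
  sites
}

# absorb border-zone nodes with no 4-connected conducting neighbor
# (pockets fully enclosed by scar) into the scar
absorb_bz_pockets <- function(scar, bz) {
  nr <- nrow(scar); nc <- ncol(scar)
  repeat {
    cond <- !scar
    orth <- matrix(FALSE, nr, nc)
    orth[-nr, ] <- orth[-nr, ] | cond[-1, ]
    orth[-1, ] <- orth[-1, ] | cond[-nr, ]
    orth[, -nc] <- orth[, -nc] | cond[, -1]
    orth[, -1] <- orth[, -1] | cond[, -nc]
    viol <- bz & !orth
    if (!any(viol)) break
    bz[viol] <- FALSE
    scar[viol] <- TRUE
  }
  list(scar = scar, bz = bz)
}

#' Construct a tissue domain directly from class matrices
#'
#' Low-level constructor used by the shipped fixtures and tests.
#'
#' @param tissue_class Integer matrix (0 normal, 1 border zone, 2 scar,
#'   3 outside) or character matrix of class names.
#' @param dx Node spacing (mm).
#' @param fiber_angle Fiber angle matrix (radians); default 0 (fibers along
#'   the apicobasal axis).
#' @param pacing_sites Matrix of 1-based `(row, col)` pacing nodes.
#' @return A `tissue_domain` object.
#' @export
tissue_domain <- function(tissue_class, dx = 0.25, fiber_angle = NULL,
                          pacing_sites = NULL) {
  if (is.character(tissue_class)) {
    tc <- matrix(TISSUE_LEVELS[tissue_class], nrow(tissue_class),
                 ncol(tissue_class))
  } else tc <- tissue_class
  storage.mode(tc) <- "integer"
  if (is.null(fiber_angle)) fiber_angle <- matrix(0, nrow(tc), ncol(tc))
  if (!is.null(pacing_sites)) {
    pacing_sites <- matrix(as.integer(pacing_sites), ncol = 2,
                           dimnames = list(NULL, c("row", "col")))
    for (i in seq_len(nrow(pacing_sites)))
      if (tc[pacing_sites[i, 1], pacing_sites[i, 2]] ==
          TISSUE_LEVELS[["scar"]])
        stop("pacing sites must be non-scar nodes")
  }
  structure(list(tissue_class = tc, fiber_angle = fiber_angle, dx = dx,
                 params = NULL, pacing_sites = pacing_sites),
            class = "tissue_domain")
}

#' Logical mask of one tissue class
#' @param domain A `tissue_domain`.
#' @param class One of `"normal"`, `"border_zone"`, `"scar"`, `"outside"`,
#'   or `"conducting"` (normal or border zone).
#' @return Logical matrix.
#' @export
tissue_mask <- function(domain, class) {
  tc <- domain$tissue_class
  if (class == "conducting")
    tc == TISSUE_LEVELS[["normal"]] | tc == TISSUE_LEVELS[["border_zone"]]
  else
    tc == TISSUE_LEVELS[[class]]
}

#' @export
print.tissue_domain <- function(x, ...) {
  s <- summarize_substrate(x)
  cat(sprintf(
    "<tissue_domain> %d x %d nodes @ %.3g mm | scar %.1f%%, border zone %.1f%% of myocardium | %d scar component(s), %d channel(s), %d pacing site(s)\n",
    nrow(x$tissue_class), ncol(x$tissue_class), x$dx,
    100 * s$scar_fraction, 100 * s$bz_fraction, s$n_scar_components,
    s$n_channels, if (is.null(x$pacing_sites)) 0L else nrow(x$pacing_sites)))
  invisible(x)
}

#' Summarize a substrate
#'
#' @param domain A `tissue_domain`.
#' @return List with `scar_fraction` and `bz_fraction` (relative to
#'   non-outside nodes), `n_scar_components` (8-connected), and
#'   `n_channels`: conducting corridors through the scar region, found by
#'   morphologically closing the scar mask and counting conducting
#'   components inside the closed region that reach the exterior through
#'   two or more separate mouths.
#' @export
summarize_substrate <- function(domain) {
  tc <- domain$tissue_class
  myo <- tc != TISSUE_LEVELS[["outside"]]
  scar <- tissue_mask(domain, "scar")
  bz <- tissue_mask(domain, "border_zone")
  n_myo <- sum(myo)
  n_comp <- if (any(scar)) max(cpp_label_components(scar, 8L)) else 0L
  list(scar_fraction = sum(scar) / n_myo, bz_fraction = sum(bz) / n_myo,
       n_scar_components = n_comp, n_channels = count_channels(domain))
}

# Conducting corridors through the scar region: morphologically close the
# scar mask and count conducting components inside the closed region that
# reach the exterior through >= 2 separate mouths. The closing radius is
# scanned upward from the requested channel width so both carved channels
# and wide natural corridors between scar lobes are found.
count_channels <- function(domain) {
  scar <- tissue_mask(domain, "scar")
  if (!any(scar)) return(0L)
  cond <- tissue_mask(domain, "conducting")
  rc0 <- ceiling(max(domain$params$channel_min_width %||% 1, 1) /
                   domain$dx) + 2
  for (rc in unique(c(rc0, 2 * rc0, 3 * rc0))) {
    closed <- !cpp_dilate_disc(!cpp_dilate_disc(scar, rc), rc)  # closing
    inside <- closed & cond
    if (!any(inside)) next
    lab <- cpp_label_components(inside, 8L)
    n_ch <- 0L
    ext <- cond & !closed
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      # contact nodes: component nodes adjacent to conducting nodes
      # outside the closed scar region
      touch <- comp & cpp_dilate_disc(ext, 1.5)
      if (!any(touch)) next
      n_mouths <- max(cpp_label_components(touch, 8L))
      if (n_mouths >= 2) n_ch <- n_ch + 1L
    }
    if (n_ch > 0) return(n_ch)
  }
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate tissue-domain invariants
#'
#' Checks that every border-zone node is 4-connected to at least one other
#' conducting node, that pacing sites are non-scar, and (when channels were
#' requested) that at least one conducting channel traverses the scar.
#'
#' @param domain A `tissue_domain`.
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_domain <- function(domain) {
  tc <- domain$tissue_class
  bz <- tissue_mask(domain, "border_zone")
  cond <- tissue_mask(domain, "conducting")
  if (any(bz)) {
    # a node is 4-connected to a conducting node iff some orthogonal
    # neighbor conducts
    nr <- nrow(tc); nc <- ncol(tc)
    pad <- function(m, dr, dc) {
      out <- matrix(FALSE, nr, nc)
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
      out
    }
    orth <- pad(cond, 1, 0) | pad(cond, -1, 0) | pad(cond, 0, 1) |
      pad(cond, 0, -1)
    if (any(bz & !orth))
      stop("isolated border-zone node (no 4-connected conducting neighbor)")
  }
  if (!is.null(domain$pacing_sites)) {
    for (i in seq_len(nrow(domain$pacing_sites))) {
      p <- domain$pacing_sites[i, ]
      if (tc[p[1], p[2]] == TISSUE_LEVELS[["scar"]])
        stop("pacing site on scar")
    }
  }
  if (!is.null(domain$params) && domain$params$n_channels > 0 &&
      any(tissue_mask(domain, "scar")))
    if (count_channels(domain) < 1)
      stop("no conducting channel traverses the scar")
  invisible(TRUE)
}

#' Write a substrate to disk (JSON header + text grids)
#'
#' Writes `<stem>.json` (shape, dx, seed, params, 0-based pacing sites;
#' row-major serialization order) plus `<stem>.tissue.txt` and
#' `<stem>.fiber.txt` whitespace-delimited grids.
#'
#' @param domain A `tissue_domain`.
#' @param stem Output path stem.
#' @return Invisibly, the header path.
#' @export
write_substrate <- function(domain, stem) {
  hdr <- list(shape = dim(domain$tissue_class), dx = domain$dx,
              seed = domain$params$rng_seed %||% NA,
              params = if (!is.null(domain$params)) unclass(domain$params),
              pacing_sites_0based =
                if (!is.null(domain$pacing_sites)) domain$pacing_sites - 1L,
              order = "row-major", indexing = "0-based")
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  write.table(domain$tissue_class, paste0(stem, ".tissue.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(signif(domain$fiber_angle, 8), paste0(stem, ".fiber.txt"),
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(stem, ".json"))
}

#' Read a substrate written by [write_substrate()]
#' @param stem Path stem used when writing.
#' @return A `tissue_domain`.
#' @export
read_substrate <- function(stem) {
  hdr <- jsonlite::fromJSON(paste0(stem, ".json"))
  tc <- as.matrix(read.table(paste0(stem, ".tissue.txt")))
  fa <- as.matrix(read.table(paste0(stem, ".fiber.txt")))
  dimnames(tc) <- NULL; dimnames(fa) <- NULL
  ps <- if (!is.null(hdr$pacing_sites_0based))
    matrix(as.integer(hdr$pacing_sites_0based), ncol = 2) + 1L
  dom <- tissue_domain(tc, dx = hdr$dx, fiber_angle = fa, pacing_sites = ps)
  if (!is.null(hdr$params)) {
    pr <- hdr$params
    dom$params <- do.call(substrate_params, pr[intersect(names(pr),
      names(formals(substrate_params)))])
  }
  dom
}

#' Export node fields as a legacy ASCII VTK structured-points file
#'
#' @param fields Named list of numeric matrices (same shape).
#' @param file Output path.
#' @param dx Node spacing (mm).
#' @return Invisibly, `file`.
#' @export
write_vtk_grid <- function(fields, file, dx = 0.25) {
  stopifnot(length(fields) >= 1)
  d <- dim(fields[[1]])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vtgrad grid export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", d[1], d[2]),
               "ORIGIN 0 0 0", sprintf("SPACING %g %g 1", dx, dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    v <- fields[[nm]]
    v[is.na(v)] <- -1e30
    writeLines(paste(format(as.vector(v), trim = TRUE), collapse = " "), con)
  }
  invisible(file)
}
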