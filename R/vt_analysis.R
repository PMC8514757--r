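# VT circuit analysis: activation maps from voltage movies, reentry
# detection (>= 2 reentrant cycles), 8-isochrone segmentation anchored at
# the circuit exit, block lines, exit sites, pathway tracing, and circuit
# comparison across model variants.

#' Activation events in a voltage movie
#'
#' All -40 mV upward crossings per node, linearly interpolated between
#' frames.
#'
#' @param movie A `voltage_movie` with recorded frames.
#' @param window Optional `c(t_start, t_end)` (ms).
#' @param threshold Upstroke threshold (mV).
#' @param max_stride Largest admissible frame stride (ms) for activation
#'   analysis.
#' @return Data frame with `node` (compact index), `t` (ms).
#' @export
activation_events <- function(movie, window = NULL, threshold = -40,
                              max_stride = 2) {
  if (!length(movie$frame_t))
    stop("movie has no recorded frames")
  stride <- unique(round(diff(movie$frame_t), 6))
  if (max(stride) > max_stride + 1e-9)
    stop(sprintf("resolution error: frame stride %.3g ms exceeds %g ms",
                 max(stride), max_stride))
  fr <- movie$frames
  tt <- movie$frame_t
  keep <- if (is.null(window)) seq_along(tt)
          else which(tt >= window[1] - max(stride) & tt <= window[2])
  if (length(keep) < 2) return(data.frame(node = integer(0), t = numeric(0)))
  out_node <- integer(0); out_t <- numeric(0)
  for (k in head(keep, -1)) {
    v1 <- fr[, k]; v2 <- fr[, k + 1]
    hit <- which(v1 < threshold & v2 >= threshold)
    if (length(hit)) {
      tc <- tt[k] + (tt[k + 1] - tt[k]) * (threshold - v1[hit]) /
        (v2[hit] - v1[hit])
      out_node <- c(out_node, hit); out_t <- c(out_t, tc)
    }
  }
  df <- data.frame(node = out_node, t = out_t)
  if (!is.null(window)) df <- df[df$t >= window[1] & df$t <= window[2], ]
  df[order(df$node, df$t), ]
}

frame_activation_times <- function(movie) activation_events(movie)$t

#' Local activation time (LAT) map for one cycle
#'
#' @param movie A `voltage_movie`.
#' @param window `c(t_start, t_end)` of the analyzed cycle (ms).
#' @param threshold Upstroke threshold (mV).
#' @return List: `lat` (grid matrix of first crossings in the window, `NA`
#'   sentinel for unactivated/scar/outside), `events` (all crossings),
#'   `cycle_window`.
#' @export
compute_lat <- function(movie, window, threshold = -40) {
  ev <- activation_events(movie, window, threshold)
  lat <- matrix(NA_real_, movie$shape[1], movie$shape[2])
  if (nrow(ev)) {
    first <- ev[!duplicated(ev$node), ]
    lat[movie$nodes[first$node]] <- first$t
  }
  list(lat = lat, events = ev, cycle_window = window)
}

#' Detect reentry in a post-stimulus window
#'
#' Reentry requires at least two stimulus-free activations over a
#' spatially spread set of nodes plus loop closure, operationalized as
#' full phase coverage: within the dominant cycle, activation times must
#' occupy at least `phase_cover` of the cycle's phase bins (a circulating
#' wavefront activates tissue at every phase of its cycle, a repetitive
#' focal source does not).
#'
#' @param movie A `voltage_movie` with frames covering the window.
#' @param post_stimulus_window `c(t_start, t_end)` beginning after the
#'   final stimulus (ms).
#' @param min_frac Minimum fraction of conducting nodes that must reach a
#'   given activation count for it to define `n_cycles`.
#' @param spread_frac Minimum fraction of conducting nodes activated at
#'   all.
#' @param phase_cover Required fraction of occupied phase bins.
#' @return List `reentry` (logical), `n_cycles`, `cycle_length` (ms, `NA`
#'   when fewer than two cycles).
#' @export
detect_reentry <- function(movie, post_stimulus_window, min_frac = 0.05,
                           spread_frac = 0.10, phase_cover = 0.75) {
  ev <- activation_events(movie, post_stimulus_window)
  n_cond <- length(movie$nodes)
  if (!nrow(ev))
    return(list(reentry = FALSE, n_cycles = 0L, cycle_length = NA_real_))
  cnt <- table(ev$node)
  n_cycles <- 0L
  for (k in seq_len(max(cnt)))
    if (sum(cnt >= k) >= min_frac * n_cond) n_cycles <- k
  spread <- length(cnt) / n_cond
  if (n_cycles < 2 || spread < spread_frac)
    return(list(reentry = FALSE, n_cycles = n_cycles,
                cycle_length = NA_real_))
  reps <- as.integer(names(cnt)[cnt >= 2])
  gaps <- unlist(lapply(split(ev$t[ev$node %in% reps], ev$node[ev$node %in% reps]),
                        diff))
  cl <- median(gaps)
  phases <- ((ev$t - post_stimulus_window[1]) %% cl) / cl
  nb <- 16
  cover <- length(unique(pmin(floor(phases * nb), nb - 1))) / nb
  list(reentry = cover >= phase_cover, n_cycles = n_cycles,
       cycle_length = cl)
}

#' Segment a LAT map into 8 isochrones anchored at the circuit exit
#'
#' Eight equal-width bins over `[exit_time - cycle_length, exit_time]`;
#' the label is the bin index of the LAT modulo the cycle, so bin 1 is the
#' earliest activation and bin 8 ends exactly at the exit time.
#'
#' @param lat LAT grid matrix (ms).
#' @param exit_time Time at which the wavefront exits the circuit (ms).
#' @param cycle_length VT cycle length (ms).
#' @return Integer grid matrix with labels 1..8 (`NA` off-circuit).
#' @export
segment_isochrones <- function(lat, exit_time, cycle_length) {
  if (!is.finite(cycle_length) || cycle_length <= 0)
    stop("cycle_length must be positive")
  ph <- (lat - (exit_time - cycle_length)) %% cycle_length
  lab <- floor(ph / (cycle_length / 8)) + 1
  lab[lab > 8] <- 8
  mode(lab) <- "integer"
  lab
}

neighbor_shift <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Locate conduction block lines on a LAT map
#'
#' Two kinds of block are reported as chains of node pairs whose circular
#' LAT difference (modulo the cycle) exceeds `block_threshold`: functional
#' block between adjacent activated nodes, and anatomical block across
#' non-conducting walls - along each grid line, the two activated nodes
#' flanking a run of scar/outside nodes form a pair (the lateral
#' boundaries of a protected channel are the canonical case). Using the
#' circular difference discards the head-tail wrap of the activation
#' sequence (a windowing artifact of wavefront curvature), while true
#' block - tissue activating about half a cycle apart across a line - is
#' retained.
#'
#' @param lat LAT grid (ms).
#' @param cycle_length VT cycle length (ms).
#' @param block_threshold Threshold (ms); default 30% of the cycle length.
#' @param domain Optional `tissue_domain`; enables the anatomical-wall
#'   search.
#' @return List of block lines, each a matrix of node-pair rows (columns
#'   `r1, c1, r2, c2`).
#' @export
locate_block_lines <- function(lat, cycle_length,
                               block_threshold = 0.3 * cycle_length,
                               domain = NULL) {
  nr <- nrow(lat); nc <- ncol(lat)
  circ_big <- function(a, b) {
    dd <- abs(a - b)
    dd <- pmin(dd, cycle_length - dd)
    !is.na(dd) & dd > block_threshold
  }
  pairs <- NULL
  for (d in list(c(1, 0), c(0, 1))) {
    nb <- neighbor_shift(lat, d[1], d[2])
    hit <- which(circ_big(lat, nb), arr.ind = TRUE)
    if (nrow(hit))
      pairs <- rbind(pairs, cbind(hit, hit[, 1] + d[1], hit[, 2] + d[2]))
  }
  if (!is.null(domain)) {
    cond <- tissue_mask(domain, "conducting")
    scan_line <- function(rs, cs) {
      # rs, cs: node coordinates along one grid line, in order
      li <- lat[cbind(rs, cs)]
      ci <- cond[cbind(rs, cs)]
      act <- which(!is.na(li))
      out <- NULL
      if (length(act) < 2) return(out)
      for (k in seq_len(length(act) - 1)) {
        i1 <- act[k]; i2 <- act[k + 1]
        if (i2 - i1 < 2) next
        between <- (i1 + 1):(i2 - 1)
        if (any(ci[between])) next  # a conducting gap is not a wall
        dd <- abs(li[i1] - li[i2])
        dd <- min(dd, cycle_length - dd)
        if (dd > block_threshold)
          out <- rbind(out, c(rs[i1], cs[i1], rs[i2], cs[i2]))
      }
      out
    }
    for (r in seq_len(nr))
      pairs <- rbind(pairs, scan_line(rep(r, nc), seq_len(nc)))
    for (c in seq_len(nc))
      pairs <- rbind(pairs, scan_line(seq_len(nr), rep(c, nr)))
  }
  if (is.null(pairs) || !nrow(pairs)) return(list())
  colnames(pairs) <- c("r1", "c1", "r2", "c2")
  # chain offending pairs into polylines by first-endpoint connectivity
  n <- nrow(pairs)
  comp <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      near <- which(comp == 0 &
                      ((abs(pairs[, 1] - pairs[k, 1]) <= 2 &
                          abs(pairs[, 2] - pairs[k, 2]) <= 2) |
                         (abs(pairs[, 3] - pairs[k, 3]) <= 2 &
                            abs(pairs[, 4] - pairs[k, 4]) <= 2)))
      comp[near] <- cur
      queue <- c(queue, near)
    }
  }
  lapply(seq_len(cur), function(k) pairs[comp == k, , drop = FALSE])
}

#' Protected (channel) border-zone mask
#'
#' Border-zone nodes flanked by scar or outside tissue on both opposite
#' sides within `span` nodes along some grid axis - the protected
#' corridor tissue of a conducting channel, as opposed to the exposed
#' border-zone rim around the scar.
#'
#' @param domain A `tissue_domain`.
#' @param span Search depth (nodes).
#' @return Logical matrix.
#' @export
protected_bz_mask <- function(domain, span = 8) {
  bz <- tissue_mask(domain, "border_zone")
  blocked <- tissue_mask(domain, "scar") | tissue_mask(domain, "outside")
  out <- matrix(FALSE, nrow(bz), ncol(bz))
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    pos <- matrix(FALSE, nrow(bz), ncol(bz))
    neg <- pos
    for (m in seq_len(span)) {
      pos <- pos | neighbor_shift(blocked, m * d[1], m * d[2], fill = FALSE)
      neg <- neg | neighbor_shift(blocked, -m * d[1], -m * d[2],
                                  fill = FALSE)
    }
    out <- out | (bz & pos & neg)
  }
  out
}

#' Locate VT exit sites
#'
#' Automated surrogate for manual annotation: the earliest-activated
#' normal-tissue nodes whose activation is causally fed (LAT-increasing
#' adjacency) from protected channel/border-zone circuit tissue (see
#' [protected_bz_mask()]). When the movie's activation events are
#' supplied, a local-precedence filter removes channel *entrances*: a true
#' exit is the first normal activation in its neighborhood, whereas at an
#' entrance the surrounding myocardium activated just before the mouth.
#' Candidates are clustered by adjacency; each cluster whose earliest LAT
#' lies within `late_window` of the global earliest candidate is one exit
#' site, so a channel conducting through two mouths reports two exits.
#'
#' @param lat LAT grid (ms).
#' @param domain The `tissue_domain`.
#' @param max_step Largest causal LAT step between adjacent nodes (ms).
#' @param late_window Secondary exits must be within this window (ms) of
#'   the earliest exit; default an eighth of the LAT range.
#' @param feed Optional logical mask of circuit tissue that can feed an
#'   exit; defaults to the protected border zone plus the border-zone rim
#'   it drains through.
#' @param events Optional activation events (`movie` crossings data frame
#'   with `node`, `t`) enabling the local-precedence filter.
#' @param nodes Compact node index of the movie (required with `events`).
#' @param radius_mm Neighborhood radius of the precedence filter (mm).
#' @return List: `sites` matrix of `(row, col)`, `times` (ms); empty with
#'   a warning when no normal-tissue activation is fed by the circuit.
#' @export
locate_exit_site <- function(lat, domain, max_step = 50,
                             late_window = NULL, feed = NULL,
                             events = NULL, nodes = NULL,
                             radius_mm = 1.5) {
  normal <- tissue_mask(domain, "normal")
  if (is.null(feed)) {
    # the protected channel plus the border-zone tissue it drains through
    bz <- tissue_mask(domain, "border_zone")
    feed <- cpp_dilate_disc(protected_bz_mask(domain), 2.9) & bz
  }
  cand <- matrix(FALSE, nrow(lat), ncol(lat))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_lat <- neighbor_shift(lat, dr, dc)
    nb_feed <- neighbor_shift(feed, dr, dc, fill = FALSE)
    ok <- normal & !is.na(lat) & nb_feed & !is.na(nb_lat) &
      nb_lat <= lat & lat - nb_lat <= max_step
    cand <- cand | ok
  }
  if (any(cand) && !is.null(events) && !is.null(nodes)) {
    # entrance filter: drop candidates whose normal neighborhood already
    # activated 2-40 ms before them (the wave arrived sideways, it is not
    # emerging from the channel)
    rad <- radius_mm / domain$dx
    which_cand <- which(cand, arr.ind = TRUE)
    ev_normal <- events[normal[nodes[events$node]], ]
    ev_r <- ((nodes[ev_normal$node] - 1) %% nrow(lat)) + 1
    ev_c <- ((nodes[ev_normal$node] - 1) %/% nrow(lat)) + 1
    for (i in seq_len(nrow(which_cand))) {
      r <- which_cand[i, 1]; c <- which_cand[i, 2]
      tn <- lat[r, c]
      near <- (ev_r - r)^2 + (ev_c - c)^2 <= rad^2
      pre <- ev_normal$t[near] >= tn - 40 & ev_normal$t[near] <= tn - 2
      if (any(pre)) cand[r, c] <- FALSE
    }
  }
  if (!any(cand)) {
    warning("no normal-tissue activation fed by circuit tissue")
    return(list(sites = matrix(numeric(0), 0, 2), times = numeric(0)))
  }
  if (is.null(late_window))
    late_window <- diff(range(lat, na.rm = TRUE)) / 8
  lab <- cpp_label_components(cand, 8L)
  sites <- NULL; times <- numeric(0)
  for (k in seq_len(max(lab))) {
    sel <- which(lab == k, arr.ind = TRUE)
    tk <- lat[lab == k]
    j <- which.min(tk)
    sites <- rbind(sites, sel[j, ])
    times <- c(times, tk[j])
  }
  keep <- times <= min(times) + late_window
  list(sites = matrix(sites[keep, ], ncol = 2,
                      dimnames = list(NULL, c("row", "col"))),
       times = times[keep])
}

# follow the activation sequence from the latest-activated circuit node
# until the walk closes on itself: at each step move to the neighbor with
# the smallest positive circular LAT increment, preferring nodes that hug
# the scar/border-zone corridor; when boxed in, jump within radius 2
trace_pathway <- function(lat, cycle_length, domain, start = NULL,
                          max_steps = 5000) {
  nr <- nrow(lat); nc <- ncol(lat)
  hug <- cpp_dilate_disc(tissue_mask(domain, "scar") |
                           tissue_mask(domain, "border_zone"), 2.2)
  if (is.null(start)) {
    # latest-activated node on the circuit corridor (fall back to global)
    idx <- which(!is.na(lat) & hug)
    if (!length(idx)) idx <- which(!is.na(lat))
    if (!length(idx)) return(matrix(integer(0), 0, 2))
    start_i <- idx[which.max(lat[idx])]
    start <- c((start_i - 1) %% nr + 1, (start_i - 1) %/% nr + 1)
  }
  path <- matrix(NA_integer_, max_steps, 2)
  path[1, ] <- start
  cur <- start
  visited <- matrix(FALSE, nr, nc)
  step_of <- function(radius) {
    t_cur <- lat[cur[1], cur[2]]
    best <- NULL; best_d <- Inf
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      r2 <- cur[1] + dr; c2 <- cur[2] + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      tl <- lat[r2, c2]
      if (is.na(tl) || visited[r2, c2]) next
      d <- (tl - t_cur) %% cycle_length
      if (d <= 1e-9 || d > cycle_length / 4) next
      bias <- if (hug[r2, c2]) 0 else cycle_length / 8
      if (d + bias < best_d) { best_d <- d + bias; best <- c(r2, c2) }
    }
    best
  }
  for (s in 2:max_steps) {
    best <- step_of(1)
    if (is.null(best)) best <- step_of(2)
    if (is.null(best)) break
    path[s, ] <- best
    visited[best[1], best[2]] <- TRUE
    cur <- best
    if (s > 10 && sqrt(sum((best - start)^2)) <= 3) {
      path <- path[seq_len(s), , drop = FALSE]
      return(rbind(path, start))
    }
  }
  path[!is.na(path[, 1]), , drop = FALSE]
}

polygon_area_signed <- function(path) {
  x <- path[, 1]; y <- path[, 2]
  n <- nrow(path)
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

point_in_polygon <- function(pt, path) {
  x <- path[, 1]; y <- path[, 2]
  n <- nrow(path)
  j <- c(n, seq_len(n - 1))
  cross <- (y > pt[2]) != (y[j] > pt[2])
  xin <- pt[1] < (x[j] - x) * (pt[2] - y) / (y[j] - y) + x
  sum(cross & xin) %% 2 == 1
}

classify_morphology <- function(path, domain) {
  if (nrow(path) < 8) return("other")
  scar <- tissue_mask(domain, "scar")
  if (!any(scar)) return("other")
  lab <- cpp_label_components(scar, 8L)
  ncomp <- max(lab)
  enc <- 0
  for (k in seq_len(ncomp)) {
    sel <- which(lab == k, arr.ind = TRUE)
    cen <- colMeans(sel)
    if (point_in_polygon(cen, path)) enc <- enc + 1
  }
  # isthmus run: a pathway node flanked by >= 2 distinct scar components
  # within a channel-scale window is the figure-of-eight signature
  isthmus <- FALSE
  win <- 8
  if (ncomp >= 2) {
    for (i in seq_len(nrow(path))) {
      r <- path[i, 1]; c <- path[i, 2]
      rs <- max(1, r - win):min(nrow(scar), r + win)
      near_r <- unique(lab[rs, path[i, 2]])
      cs <- max(1, c - win):min(ncol(scar), c + win)
      near_c <- unique(lab[path[i, 1], cs])
      if (sum(near_r > 0) >= 2 || sum(near_c > 0) >= 2) {
        isthmus <- TRUE
        break
      }
    }
  }
  if (isthmus) "double_loop"
  else if (enc >= 1) "single_loop"
  else "other"
}

#' Analyze an induced VT into a circuit description
#'
#' Computes the activation map of one late cycle, anchors the cycle at the
#' circuit exit time, segments 8 isochrones, locates block lines and exit
#' sites, traces the reentry pathway (starting from and ending at the
#' latest activation), and classifies the morphology.
#'
#' @param outcome An `induction_outcome` with `vt_induced = TRUE` (or a
#'   `voltage_movie` plus explicit `window`).
#' @param domain The `tissue_domain`.
#' @param window Optional `c(t_start, t_end)` post-stimulus analysis
#'   window; defaults to the movie's frame coverage after the final
#'   stimulus.
#' @param block_threshold_frac Block threshold as a fraction of the cycle
#'   length.
#' @return Object of class `vt_circuit`.
#' @export
analyze_vt <- function(outcome, domain, window = NULL,
                       block_threshold_frac = 0.3) {
  movie <- if (inherits(outcome, "induction_outcome")) outcome$movie
           else outcome
  if (is.null(window)) {
    w0 <- if (inherits(outcome, "induction_outcome") &&
              !is.null(outcome$t_last_stimulus))
      outcome$t_last_stimulus + 5 else movie$frame_t[1]
    window <- c(max(w0, movie$frame_t[1]), movie$t1)
  }
  det <- detect_reentry(movie, window)
  if (!det$reentry)
    return(structure(list(reentry = FALSE, n_cycles = det$n_cycles,
                          cycle_length = det$cycle_length),
                     class = "vt_circuit"))
  cl <- det$cycle_length
  # provisional late-cycle LAT map, ending at the last activity (the VT
  # may have self-terminated before the recorded horizon)
  t_last_act <- max(activation_events(movie, window)$t)
  w_end <- max(min(window[2], t_last_act + 2) - 5, window[1] + cl + 2)
  prov <- compute_lat(movie, c(w_end - cl, w_end))
  ex0 <- locate_exit_site(prov$lat, domain, events = prov$events,
                          nodes = movie$nodes)
  exit_time <- if (length(ex0$times)) min(ex0$times) else w_end
  # anchored cycle: bin 8 ends exactly at the exit time of the previous
  # full cycle inside the window
  while (exit_time - cl < window[1] + 1) exit_time <- exit_time + cl
  if (exit_time > w_end) exit_time <- exit_time - cl
  anchored <- compute_lat(movie, c(exit_time - cl, exit_time))
  lat <- anchored$lat
  iso <- segment_isochrones(lat, exit_time, cl)
  blocks <- locate_block_lines(lat, cl, block_threshold_frac * cl,
                               domain = domain)
  exits <- locate_exit_site(lat, domain, events = anchored$events,
                            nodes = movie$nodes)
  path <- trace_pathway(lat, cl, domain)
  structure(list(reentry = TRUE, n_cycles = det$n_cycles,
                 cycle_length = cl, pathway = path,
                 morphology = classify_morphology(path, domain),
                 block_lines = blocks, exit_sites = exits$sites,
                 exit_times = exits$times,
                 activation_map = list(lat = lat, isochrone_label = iso,
                                       cycle_window = c(exit_time - cl,
                                                        exit_time),
                                       cycle_length = cl,
                                       exit_time = exit_time),
                 shape = movie$shape, dx = movie$dx),
            class = "vt_circuit")
}

#' @export
print.vt_circuit <- function(x, ...) {
  if (!x$reentry) {
    cat("<vt_circuit> no reentry (", x$n_cycles, "cycle(s) )\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<vt_circuit> %s reentry | %d cycles, CL %.0f ms | %d block line(s), %d exit site(s), pathway %d nodes\n",
    x$morphology, x$n_cycles, x$cycle_length, length(x$block_lines),
    nrow(x$exit_sites), nrow(x$pathway)))
  invisible(x)
}

#' Compare two VT circuits on the same substrate
#'
#' Pathways match when the Jaccard overlap of their dilated pathway masks
#' reaches `pathway_overlap_threshold` and both loops run with the same
#' traversal sense (chirality); exit sites match when the smallest
#' pairwise exit distance is within `concordance_radius`.
#'
#' @param a,b `vt_circuit` objects from registered (same-geometry)
#'   domains.
#' @param concordance_radius Exit-site concordance radius (mm).
#' @param pathway_overlap_threshold Jaccard threshold.
#' @param dilate_mm Pathway mask dilation (mm).
#' @return Object of class `circuit_comparison`: `pathway_match`,
#'   `exit_site_match`, `common_channel_overlap`,
#'   `distance_between_exit_sites` (mm).
#' @export
compare_circuits <- function(a, b, concordance_radius = 5,
                             pathway_overlap_threshold = 0.7,
                             dilate_mm = 1.5) {
  if (!a$reentry || !b$reentry)
    stop("both circuits must contain detected reentry")
  if (!all(a$shape == b$shape))
    stop("comparison error: circuits live on different domain shapes")
  mask <- function(x) {
    m <- matrix(FALSE, x$shape[1], x$shape[2])
    m[x$pathway] <- TRUE
    cpp_dilate_disc(m, max(dilate_mm / x$dx, 1))
  }
  ma <- mask(a); mb <- mask(b)
  jac <- sum(ma & mb) / max(sum(ma | mb), 1)
  sense_a <- sign(polygon_area_signed(a$pathway))
  sense_b <- sign(polygon_area_signed(b$pathway))
  pathway_match <- jac >= pathway_overlap_threshold && sense_a == sense_b
  dmin <- Inf
  if (nrow(a$exit_sites) && nrow(b$exit_sites)) {
    for (i in seq_len(nrow(a$exit_sites)))
      for (k in seq_len(nrow(b$exit_sites)))
        dmin <- min(dmin, sqrt(sum((a$exit_sites[i, ] -
                                      b$exit_sites[k, ])^2)) * a$dx)
  }
  structure(list(pathway_match = pathway_match,
                 exit_site_match = is.finite(dmin) &&
                   dmin <= concordance_radius,
                 common_channel_overlap = jac,
                 distance_between_exit_sites = dmin),
            class = "circuit_comparison")
}

#' @export
print.circuit_comparison <- function(x, ...) {
  cat(sprintf(
    "<circuit_comparison> pathway %s (overlap %.2f), exit %s (min distance %.1f mm)\n",
    if (x$pathway_match) "match" else "NO match",
    x$common_channel_overlap,
    if (x$exit_site_match) "match" else "NO match",
    x$distance_between_exit_sites))
  invisible(x)
}

#' Export an activation map (and isochrone labels) as delimited text/VTK
#'
#' The 8 isochrone levels follow the gray-to-purple convention: level 1 =
#' earliest (gray), level 8 = latest (purple), anchored at the circuit
#' exit.
#'
#' @param circuit A `vt_circuit`.
#' @param stem Output path stem (writes `<stem>.lat.txt`,
#'   `<stem>.iso.txt`, `<stem>.vtk`).
#' @param dx Node spacing (mm).
#' @return Invisibly, `stem`.
#' @export
write_activation_map <- function(circuit, stem, dx = circuit$dx) {
  am <- circuit$activation_map
  write.table(am$lat, paste0(stem, ".lat.txt"), row.names = FALSE,
              col.names = FALSE)
  write.table(am$isochrone_label, paste0(stem, ".iso.txt"),
              row.names = FALSE, col.names = FALSE)
  write_vtk_grid(list(lat = am$lat,
                      isochrone = am$isochrone_label * 1.0),
                 paste0(stem, ".vtk"), dx = dx)
  invisible(stem)
}
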