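#' Find the optimal screw corridor of a bone tunnel
#'
#' Searches for the maximal inscribed cylinder: the axis (start point +
#' direction) that maximises the *bottleneck clearance*
#' `f(axis) = min over stations t in [0, length] of dmap(axis_point + t * dir)`,
#' i.e. the largest screw radius that fits the tunnel without touching
#' cortex anywhere along the axis. The minimum (not the mean) is used so that
#' a single cortical encroachment dominates the objective.
#'
#' The search is fully deterministic: a coarse stage evaluates the objective
#' on a Fibonacci-sphere grid of directions crossed with a 3x3x3 grid of
#' start-point offsets around `seed_point`, and a refinement stage runs
#' Nelder-Mead on five parameters (two direction angles, three point offsets;
#' the start point is kept within `ball_radius` of the seed by a penalty).
#' The refined optimum never falls below the best coarse candidate.
#'
#' @param dmap a [distance_map()].
#' @param seed_point 3-vector, mm; must lie inside the bone.
#' @param length corridor length, mm.
#' @param n_dirs number of Fibonacci-sphere directions (default 200).
#' @param ball_radius search radius for the start point, mm (default 10).
#' @param station_step station spacing for the objective, mm (default 1).
#' @param orient_hint direction used to resolve the axis sign: the returned
#'   `axis_dir` makes an angle <= 90 degrees with it (default world `+z`).
#' @return An object of class `corridor`: `axis_point`, `axis_dir`, `length`,
#'   `max_radius` (bottleneck clearance, mm), `clearance_profile`
#'   (data.frame station/clearance) and `objective_trace`.
#' @examples
#' ph <- make_capsule_phantom(5, 40, spacing = 1)
#' dm <- distance_map(segment_bone(ph$volume))
#' cor <- find_corridor(dm, seed_point = c(0, 0, 0), length = 30)
#' cor$max_radius
#' @export
find_corridor <- function(dmap, seed_point, length, n_dirs = 200,
                          ball_radius = 10, station_step = 1,
                          orient_hint = c(0, 0, 1)) {
  stopifnot(inherits(dmap, "distance_map"))
  seed_point <- as.numeric(seed_point)
  if (sample_field(dmap, matrix(seed_point, 1)) <= 0)
    stop("seed_point is not inside the bone mask")
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")

  dirs <- fibonacci_sphere(n_dirs)
  o1 <- c(-1, 0, 1) * ball_radius / sqrt(3)
  off <- as.matrix(expand.grid(x = o1, y = o1, z = o1))
  pts <- sweep(off, 2, seed_point, `+`)
  coarse <- .corridor_coarse_cpp(as.numeric(dmap$data), dim(dmap$data),
                                 dmap$spacing, dmap$origin, pts, dirs,
                                 length, station_step)

  # Length continuation: the direction basin of a long narrow tunnel is only
  # a few degrees wide, far narrower than the coarse direction grid, so the
  # search starts with a short corridor (wide basin), refines, and extends.
  stages <- sort(unique(pmin(length, c(12, ceiling(length * 2 / 3), length))))
  co1 <- if (stages[1] == length) coarse else
    .corridor_coarse_cpp(as.numeric(dmap$data), dim(dmap$data), dmap$spacing,
                         dmap$origin, pts, dirs, stages[1], station_step)
  if (co1$best_value <= 0 && coarse$best_value <= 0)
    stop("no corridor found: clearance is non-positive at every coarse candidate")
  # multi-start: take the best coarse candidates, but force diversity in
  # direction/position so one broad basin cannot crowd out the tunnel basin
  ord <- order(co1$objective, decreasing = TRUE)
  chosen <- integer(0)
  for (idx in ord) {
    if (co1$objective[idx] <= 0) break
    i <- (idx - 1) %% nrow(pts) + 1
    j <- (idx - 1) %/% nrow(pts) + 1
    distinct <- TRUE
    for (idx2 in chosen) {
      i2 <- (idx2 - 1) %% nrow(pts) + 1
      j2 <- (idx2 - 1) %/% nrow(pts) + 1
      ang <- acos(min(1, abs(sum(dirs[j, ] * dirs[j2, ])))) * 180 / pi
      sep <- sqrt(sum((pts[i, ] - pts[i2, ])^2))
      if (ang < 15 && sep < 4) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) chosen <- c(chosen, idx)
    if (base::length(chosen) >= 6) break
  }
  if (base::length(chosen) == 0) chosen <- ord[1]
  cands <- lapply(chosen, function(idx) {
    i <- (idx - 1) %% nrow(pts) + 1
    j <- (idx - 1) %/% nrow(pts) + 1
    refine_simplex(dmap, seed_point, ball_radius, stages[1], station_step,
                   pts[i, ], dirs[j, ])
  })
  carry <- diverse_top(cands, 3)
  L_prev <- stages[1]
  for (Lk in stages[-1]) {
    slide <- Lk - L_prev
    pool <- list()
    for (cand in carry) {
      capd <- rbind(cand$d, fib_cap_dirs(30, cand$d, 10))
      pc <- rbind(cand$p, cand$p - 0.5 * slide * cand$d,
                  cand$p - slide * cand$d)
      co <- .corridor_coarse_cpp(as.numeric(dmap$data), dim(dmap$data),
                                 dmap$spacing, dmap$origin, pc, capd, Lk,
                                 station_step)
      ordk <- order(co$objective, decreasing = TRUE)[1:2]
      pool <- c(pool, lapply(ordk, function(idx) {
        i <- (idx - 1) %% nrow(pc) + 1
        j <- (idx - 1) %/% nrow(pc) + 1
        refine_simplex(dmap, seed_point, ball_radius, Lk, station_step,
                       pc[i, ], capd[j, ])
      }))
    }
    carry <- diverse_top(pool, 3)
    L_prev <- Lk
  }
  best <- carry[[which.max(vapply(carry, `[[`, 0, "f"))]]
  refined <- list(p = best$p, d = best$d)
  f_ref <- best$f
  if (f_ref < coarse$best_value) {  # never degrade the full-length coarse optimum
    refined <- list(p = pts[coarse$best_point, ],
                    d = dirs[coarse$best_dir, ])
    f_ref <- coarse$best_value
  }
  if (f_ref <= 0)
    stop("no corridor found: clearance is non-positive at every candidate")

  # resolve the axis-sign ambiguity deterministically
  if (sum(refined$d * as.numeric(orient_hint)) < 0) {
    refined$p <- refined$p + length * refined$d
    refined$d <- -refined$d
  }
  st <- station_seq(length, station_step)
  prof <- data.frame(station = st,
                     clearance = sample_field(dmap, station_points(refined$p,
                                                                   refined$d,
                                                                   st)))
  structure(list(axis_point = refined$p, axis_dir = refined$d,
                 length = length, max_radius = min(prof$clearance),
                 clearance_profile = prof,
                 objective_trace = list(coarse_best = coarse$best_value,
                                        refined = f_ref)),
            class = "corridor")
}

station_seq <- function(length, step) {
  t <- seq(0, length, by = step)
  if (t[base::length(t)] < length - 1e-9) t <- c(t, length)
  t
}

station_points <- function(p, d, t) {
  cbind(p[1] + t * d[1], p[2] + t * d[2], p[3] + t * d[3])
}

corridor_objective <- function(dmap, p, d, length, step) {
  .corridor_coarse_cpp(as.numeric(dmap$data), dim(dmap$data), dmap$spacing,
                       dmap$origin, matrix(p, 1), matrix(d, 1), length,
                       step)$best_value
}

# Nelder-Mead polish of one candidate on (dp, alpha, beta), run at two
# parameter scales with restarts; simplex methods stall on the kinked
# min-clearance objective without them. Deterministic throughout. A corridor
# is sign-symmetric in its axis, so the ball constraint is applied to
# whichever end lies nearer the seed, and the returned candidate is
# canonicalized to start at that end.
refine_simplex <- function(dmap, seed_point, ball_radius, length, step,
                           p0, d0) {
  seg_pen <- function(p, d) {
    far <- p + length * d
    max(0, min(sqrt(sum((p - seed_point)^2)),
               sqrt(sum((far - seed_point)^2))) - ball_radius)
  }
  pcur <- p0
  dcur <- unit(d0)
  for (scale in list(c(2, 2, 2, 0.1, 0.1), c(0.5, 0.5, 0.5, 0.02, 0.02))) {
    e1 <- perp_unit(dcur)
    e2 <- cross3(dcur, e1)
    pb <- pcur
    db <- dcur
    fn <- function(x) {
      x <- x * scale
      d <- unit(db + x[4] * e1 + x[5] * e2)
      p <- pb + x[1:3]
      corridor_objective(dmap, p, d, length, step) - 100 * seg_pen(p, d)
    }
    par <- rep(0, 5)
    for (restart in 1:2) {
      opt <- stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 400,
                                         reltol = 1e-9))
      par <- opt$par
    }
    x <- par * scale
    dcur <- unit(db + x[4] * e1 + x[5] * e2)
    pcur <- pb + x[1:3]
  }
  far <- pcur + length * dcur
  if (sum((far - seed_point)^2) < sum((pcur - seed_point)^2)) {
    pcur <- far
    dcur <- -dcur
  }
  list(p = pcur, d = dcur,
       f = corridor_objective(dmap, pcur, dcur, length, step))
}

# keep the n best candidates that are mutually distinct in direction or
# position (so several objective basins survive the continuation stages)
diverse_top <- function(cands, n) {
  cands <- cands[order(vapply(cands, `[[`, 0, "f"), decreasing = TRUE)]
  keep <- list()
  for (cand in cands) {
    distinct <- TRUE
    for (k in keep) {
      ang <- acos(min(1, abs(sum(cand$d * k$d)))) * 180 / pi
      if (ang < 5 && sqrt(sum((cand$p - k$p)^2)) < 2) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) keep <- c(keep, list(cand))
    if (base::length(keep) >= n) break
  }
  keep
}

# quasi-uniform directions within ang_deg of d (Fibonacci spiral on the cap)
fib_cap_dirs <- function(n, d, ang_deg) {
  ca <- cos(ang_deg * pi / 180)
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - ca) * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  e1 <- perp_unit(d)
  e2 <- cross3(d, e1)
  outer(r * cos(phi), e1) + outer(r * sin(phi), e2) + outer(z, d)
}

#' Deterministic Fibonacci-sphere direction grid
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors, quasi-uniform on the sphere.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.corridor <- function(x, ...) {
  cat(sprintf(
    "<corridor> length %.1f mm, bottleneck radius %.2f mm\n  axis (%s) -> dir (%s)\n",
    x$length, x$max_radius,
    paste(sprintf("%.2f", x$axis_point), collapse = ", "),
    paste(sprintf("%.3f", x$axis_dir), collapse = ", ")))
  invisible(x)
}

#' @export
summary.corridor <- function(object, ...) {
  cat(sprintf(
    "Corridor: length %.1f mm, max safe radius %.2f mm\n", object$length,
    object$max_radius))
  cat(sprintf("Clearance along axis: min %.2f / median %.2f / max %.2f mm\n",
              min(object$clearance_profile$clearance),
              stats::median(object$clearance_profile$clearance),
              max(object$clearance_profile$clearance)))
  invisible(object)
}

#' Coracoid-tunnel-view from a corridor
#'
#' The optimal fluoroscopic view has the corridor axis in line with the
#' central X-ray beam: `view_dir` equals the corridor axis, the detector is
#' centred on the corridor axis, and the crosshair sits at `(0, 0)` so the
#' crosshair ray *is* the corridor axis. In this view a correctly oriented
#' screw projects as a dot.
#'
#' @param corridor a [find_corridor()] result.
#' @param geom a [projection_geometry()] (kept for provenance; the view state
#'   itself is geometry-free).
#' @return A [view_state()] with crosshair `(0, 0)`.
#' @export
ctv_from_corridor <- function(corridor, geom = projection_geometry()) {
  stopifnot(inherits(corridor, "corridor"))
  view_along(corridor$axis_dir, detector_center = corridor$axis_point,
             crosshair = c(0, 0))
}

#' Is a screw seen as a dot in this view?
#'
#' The screw-as-a-dot criterion of the tunnel view: the silhouette of the
#' screw cylinder in the view must not exceed `tol` times its cross-section
#' disc area `pi * radius^2`.
#'
#' @param cyl a [cylinder()].
#' @param view a [view_state()].
#' @param geom a [projection_geometry()]; sub-millimetre pixels recommended
#'   for thin screws.
#' @param tol area ratio threshold (> 1), default 1.10.
#' @return logical, with attribute `area_ratio`.
#' @export
screw_is_dot <- function(cyl, view, geom = projection_geometry(pixel_spacing = 0.5),
                         tol = 1.10) {
  if (!is.numeric(tol) || tol <= 1) stop("tol must be > 1")
  area <- as.numeric(silhouette_area(cyl, view, geom))
  ratio <- area / (pi * cyl$radius^2)
  structure(ratio <= tol, area_ratio = ratio)
}

#' Serialize a corridor as JSON
#'
#' @param corridor a [find_corridor()] result.
#' @param path optional file path.
#' @return JSON string, or `path` invisibly.
#' @export
corridor_to_json <- function(corridor, path = NULL) {
  js <- jsonlite::toJSON(list(axis_point = corridor$axis_point,
                              axis_dir = corridor$axis_dir,
                              length_mm = corridor$length,
                              max_radius_mm = corridor$max_radius,
                              clearance_profile = corridor$clearance_profile),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
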