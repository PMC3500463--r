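#' Stimulus parameters for the random-dot figure-ground display
#'
#' The display is a full screen of one-pixel black/white dots (each pixel
#' black with probability `dot_black_prob`). A stimulus consists of three
#' concentric rectangular regions -- background, figure frame and inner
#' figure -- centred at a fixed offset from fixation. During the two motion
#' refreshes every region's dots translate coherently by `displacement`
#' pixels along one of four diagonal directions (45, 135, 225, 315 degrees);
#' dots never cross their region border, and vacated border pixels are
#' refilled with fresh fair coin flips, so flicker is identical across
#' stimulus kinds.
#'
#' Region sizes are configured in pixels. The viewing-geometry figures the
#' design was derived from (region extents in degrees of visual angle at
#' 0.64 deg/cm and a 17-inch 1024x768 monitor at 90 cm) are carried as
#' metadata in `$degrees` and are not enforced, because the monitor pixel
#' pitch needed for an exact conversion is not part of the design.
#'
#' @param screen_size `c(width, height)` in pixels.
#' @param refresh_rate display refresh rate in Hz.
#' @param frame_extent_px side of the outer (frame) square, pixels.
#' @param inner_extent_px side of the inner figure square, pixels.
#' @param offset_px `c(x, y)` offset of the figure centre from screen
#'   centre in pixels (x positive rightward, y positive downward; the
#'   default places the figure in the lower-left quadrant).
#' @param dot_black_prob probability that a dot is black.
#' @param directions the four motion directions in degrees.
#' @param displacement pixels moved per screen refresh (0 allowed only as a
#'   degenerate no-motion configuration for audits).
#' @param n_motion_frames number of motion refreshes.
#' @param degrees metadata list of the nominal extents in degrees.
#' @return object of class `fg_stimulus_params`.
#' @export
stimulus_params <- function(screen_size = c(1024L, 768L),
                            refresh_rate = 60,
                            frame_extent_px = 153L,
                            inner_extent_px = 115L,
                            offset_px = c(-192L, 192L),
                            dot_black_prob = 0.5,
                            directions = c(45, 135, 225, 315),
                            displacement = 1L,
                            n_motion_frames = 2L,
                            degrees = list(background = 17.99, frame = 3.23,
                                           inner = 2.42, offset_h = 7.7,
                                           offset_v = 10.64,
                                           deg_per_cm = 0.64,
                                           viewing_distance_cm = 90)) {
  fg_assert(length(screen_size) == 2 && all(screen_size >= 8),
            "input", "screen_size must be two positive pixel counts")
  fg_assert(inner_extent_px < frame_extent_px,
            "geometry", "inner_extent_px (%d) must be < frame_extent_px (%d)",
            inner_extent_px, frame_extent_px)
  fg_assert(frame_extent_px < min(screen_size),
            "geometry", "frame_extent_px (%d) must fit inside the screen",
            frame_extent_px)
  fg_assert(length(directions) == 4, "input", "exactly 4 motion directions required")
  d <- sort(directions %% 360)
  fg_assert(all(abs(diff(d) - 90) < 1e-9), "input",
            "the 4 motion directions must be 90 degrees apart")
  fg_assert(displacement >= 0, "input", "displacement must be >= 0")
  fg_assert(dot_black_prob >= 0 && dot_black_prob <= 1, "input",
            "dot_black_prob must be a probability")
  structure(list(
    screen_size = as.integer(screen_size), refresh_rate = refresh_rate,
    frame_extent_px = as.integer(frame_extent_px),
    inner_extent_px = as.integer(inner_extent_px),
    offset_px = as.integer(offset_px), dot_black_prob = dot_black_prob,
    directions = directions, displacement = as.integer(displacement),
    n_motion_frames = as.integer(n_motion_frames), degrees = degrees
  ), class = "fg_stimulus_params")
}

#' Stimulus presentation duration implied by the refresh rate
#'
#' Two screen refreshes at 60 Hz give the canonical 33.3 ms presentation.
#'
#' @param params stimulus parameters.
#' @return duration in milliseconds.
#' @export
stimulus_duration_ms <- function(params = stimulus_params()) {
  params$n_motion_frames * 1000 / params$refresh_rate
}

#' Visual angle subtended by one centimetre at a viewing distance
#'
#' @param distance_cm viewing distance in cm (90 by default).
#' @return degrees of visual angle per cm of screen.
#' @export
visual_angle_per_cm <- function(distance_cm = 90) {
  2 * atan(0.5 / distance_cm) * 180 / pi
}

#' Partition the screen into background, frame and inner-figure regions
#'
#' The frame and inner regions are concentric squares centred at the
#' configured offset from screen centre; everything else is background.
#' The partition is purely geometric: it is shared by all three stimulus
#' kinds, which differ only in the motion directions assigned to the
#' regions.
#'
#' @param params stimulus parameters.
#' @return object of class `fg_region_masks`: an integer matrix
#'   (rows = y, cols = x) with values 0 = background, 1 = frame,
#'   2 = inner, plus geometry attributes.
#' @export
make_region_masks <- function(params = stimulus_params()) {
  w <- params$screen_size[1]; h <- params$screen_size[2]
  cx <- floor(w / 2) + params$offset_px[1]
  cy <- floor(h / 2) + params$offset_px[2]
  half_f <- floor(params$frame_extent_px / 2)
  half_i <- floor(params$inner_extent_px / 2)
  fx <- c(cx - half_f, cx - half_f + params$frame_extent_px - 1L)
  fy <- c(cy - half_f, cy - half_f + params$frame_extent_px - 1L)
  if (fx[1] < 1 || fy[1] < 1 || fx[2] > w || fy[2] > h) {
    fg_stop("geometry",
            "frame region [%d..%d] x [%d..%d] does not fit on the %dx%d screen",
            fx[1], fx[2], fy[1], fy[2], w, h)
  }
  ix <- c(cx - half_i, cx - half_i + params$inner_extent_px - 1L)
  iy <- c(cy - half_i, cy - half_i + params$inner_extent_px - 1L)
  m <- matrix(0L, nrow = h, ncol = w)
  m[fy[1]:fy[2], fx[1]:fx[2]] <- 1L
  m[iy[1]:iy[2], ix[1]:ix[2]] <- 2L
  structure(m, class = c("fg_region_masks", class(m)),
            center = c(cx, cy), frame_bounds = list(x = fx, y = fy),
            inner_bounds = list(x = ix, y = iy))
}

region_labels <- c("background", "frame", "inner")

#' Assign motion directions to the three regions
#'
#' Direction rules: a homogenous stimulus moves all three regions in one
#' common direction; a frame stimulus moves the frame region orthogonally
#' (+/-90 degrees) to the shared background/inner direction; a stack
#' stimulus moves the frame orthogonally to the background and the inner
#' region orthogonally to the frame and away from the background, so all
#' three directions are pairwise distinct and regions sharing a border
#' always differ by exactly 90 degrees. Non-adjacent regions (background
#' and inner in a stack) end up 180 degrees apart.
#'
#' @param kind one of `"stack"`, `"frame"`, `"homogenous"`.
#' @param params stimulus parameters.
#' @return named numeric vector `c(background=, frame=, inner=)` (degrees).
#'   Uses the current RNG stream.
#' @export
assign_directions <- function(kind, params = stimulus_params()) {
  dirs <- params$directions
  base <- sample(dirs, 1)
  rot <- function(d, k) dirs[match(((d + k) %% 360), dirs %% 360)]
  sign90 <- sample(c(90, -90), 1)
  out <- switch(kind,
    homogenous = c(base, base, base),
    frame = c(base, rot(base, sign90), base),
    stack = c(base, rot(base, sign90), rot(base, 180)),
    fg_stop("input", "unknown stimulus kind '%s'", kind)
  )
  names(out) <- region_labels
  out
}

dir_step <- function(direction, displacement) {
  # screen coordinates: x rightward, y downward; 45 deg = up-right
  direction <- unname(direction)
  c(dx = displacement * sign(round(cos(direction * pi / 180), 9)),
    dy = -displacement * sign(round(sin(direction * pi / 180), 9)))
}

# Precompute, per region, the target pixels, their source pixels one step
# back along the region's direction, and which targets must be refilled
# because their source lies outside the region (the trailing border).
shift_plan <- function(masks, assignment, displacement) {
  h <- nrow(masks); w <- ncol(masks)
  lapply(0:2, function(r) {
    d <- assignment[r + 1]
    st <- dir_step(d, displacement)
    idx <- which(masks == r)
    y <- ((idx - 1L) %% h) + 1L
    x <- ((idx - 1L) %/% h) + 1L
    sy <- y - st["dy"]; sx <- x - st["dx"]
    on_screen <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
    src <- (pmax(pmin(sx, w), 1) - 1L) * h + pmax(pmin(sy, h), 1)
    inside <- on_screen & masks[src] == r
    list(idx = idx, src = src, inside = inside)
  })
}

apply_shift <- function(img, plan, dot_black_prob) {
  out <- img
  refill <- integer(0)
  for (p in plan) {
    vals <- integer(length(p$idx))
    vals[p$inside] <- img[p$src[p$inside]]
    n_fill <- sum(!p$inside)
    if (n_fill > 0) vals[!p$inside] <- rbinom(n_fill, 1, dot_black_prob)
    out[p$idx] <- vals
    refill <- c(refill, p$idx[!p$inside])
  }
  list(img = out, refill = refill)
}

#' Generate one random-dot figure-ground stimulus movie
#'
#' Produces a 4-frame movie: the pre-stimulus static dot field, the two
#' motion refreshes, and the post-stimulus static frame (identical to the
#' last motion frame -- after the second displacement all dots remain in
#' position; the continuing static display is represented by this single
#' held frame). Within each region dots translate coherently by
#' `displacement` pixels per refresh along the region's direction; dots
#' whose source would cross the region border are deleted and the vacated
#' pixels refilled i.i.d. black/white, reproducing the (dis)appearing-dot
#' flicker shared by all stimulus kinds.
#'
#' @param kind `"stack"`, `"frame"` or `"homogenous"`.
#' @param params stimulus parameters.
#' @param seed integer seed; the movie is a pure function of
#'   `(kind, params, seed)`.
#' @param materialize if `FALSE`, draw only the direction assignment and
#'   skip pixel generation (cheap mode for balance audits; `frames` is
#'   `NULL`). The assignment is identical to the materialized movie with
#'   the same seed.
#' @return object of class `fg_movie`: list with `frames` (list of 4
#'   integer matrices, 1 = black), `masks`, `assignment`, `kind`, `seed`,
#'   `refill` (per motion step, linear indices of refilled pixels), and
#'   `params`.
#' @export
generate_stimulus <- function(kind, params = stimulus_params(), seed = 1L,
                              materialize = TRUE) {
  fg_assert(kind %in% c("stack", "frame", "homogenous"), "input",
            "unknown stimulus kind '%s'", as.character(kind)[1])
  set.seed(as.integer(seed))
  assignment <- assign_directions(kind, params)
  frames <- NULL; refill <- NULL
  if (materialize) {
    masks <- make_region_masks(params)
    h <- nrow(masks); w <- ncol(masks)
    f1 <- matrix(rbinom(h * w, 1, params$dot_black_prob), nrow = h)
    plan <- shift_plan(masks, assignment, params$displacement)
    frames <- vector("list", params$n_motion_frames + 2L)
    refill <- vector("list", params$n_motion_frames)
    frames[[1]] <- f1
    cur <- f1
    for (k in seq_len(params$n_motion_frames)) {
      sh <- apply_shift(cur, plan, params$dot_black_prob)
      cur <- sh$img
      frames[[k + 1]] <- cur
      refill[[k]] <- sh$refill
    }
    frames[[params$n_motion_frames + 2L]] <- cur # post-stimulus hold
  }
  structure(list(frames = frames, masks = if (materialize) masks else NULL,
                 assignment = assignment, kind = kind, seed = as.integer(seed),
                 refill = refill, params = params),
            class = "fg_movie")
}

#' Summarize motion energy over a collection of movies
#'
#' For each stimulus kind, counts region-pixels displaced in each of the
#' four directions (region area x motion refreshes, attributed to the
#' region's assigned direction), aggregated over movies. Uses only masks
#' and direction assignments, so it works on non-materialized movies.
#'
#' @param movies list of `fg_movie` objects (>= 1 per kind present).
#' @return data.frame with columns `kind`, `direction`, `pixels_moved`,
#'   `share` (within kind).
#' @export
motion_energy_summary <- function(movies) {
  fg_assert(length(movies) > 0, "input", "no movies supplied")
  params <- movies[[1]]$params
  masks <- movies[[1]]$masks %||% make_region_masks(params)
  area <- tabulate(as.vector(masks) + 1L, nbins = 3L)
  dirs <- sort(params$directions %% 360)
  rows <- lapply(movies, function(m) {
    px <- vapply(seq_along(dirs), function(i) {
      sum(area[m$assignment %% 360 == dirs[i]]) * params$n_motion_frames
    }, numeric(1))
    data.frame(kind = m$kind, direction = dirs, pixels_moved = px)
  })
  out <- do.call(rbind, rows)
  agg <- aggregate(pixels_moved ~ kind + direction, out, sum)
  tot <- aggregate(pixels_moved ~ kind, agg, sum)
  agg$share <- agg$pixels_moved / tot$pixels_moved[match(agg$kind, tot$kind)]
  agg[order(agg$kind, agg$direction), ]
}

#' Audit flicker produced by (dis)appearing dots
#'
#' Counts pixels whose value changes between consecutive motion frames,
#' split into border-refill flicker (pixels refilled because a dot was
#' deleted at the region border) and interior translation changes. The
#' design guarantees equal expected border-refill flicker across stimulus
#' kinds, since all kinds share the same region geometry and displacement
#' magnitude.
#'
#' @param movies list of materialized `fg_movie` objects.
#' @return data.frame per kind: mean `border_refill_changed`,
#'   `interior_changed` and `total_changed` per motion step.
#' @export
flicker_audit <- function(movies) {
  fg_assert(length(movies) > 0, "input", "no movies supplied")
  fg_assert(all(vapply(movies, function(m) !is.null(m$frames), logical(1))),
            "input", "flicker_audit needs materialized movies")
  rows <- lapply(movies, function(m) {
    nm <- m$params$n_motion_frames
    border <- interior <- 0
    for (k in seq_len(nm)) {
      a <- m$frames[[k]]; b <- m$frames[[k + 1]]
      changed <- which(a != b)
      rf <- m$refill[[k]]
      border <- border + sum(changed %in% rf)
      interior <- interior + length(changed) - sum(changed %in% rf)
    }
    data.frame(kind = m$kind, border_refill_changed = border / nm,
               interior_changed = interior / nm)
  })
  out <- do.call(rbind, rows)
  agg <- aggregate(cbind(border_refill_changed, interior_changed) ~ kind,
                   out, mean)
  agg$total_changed <- agg$border_refill_changed + agg$interior_changed
  agg
}

#' Write a movie's frames as PGM images (and masks as a PGM)
#'
#' Lossless plain-text export for inspection/documentation.
#'
#' @param movie `fg_movie`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_movie <- function(movie, dir) {
  fg_assert(!is.null(movie$frames), "input", "movie has no materialized frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pgm <- function(m, path, maxval = 1L) {
    con <- file(path, "w")
    on.exit(close(con))
    cat("P2\n", ncol(m), " ", nrow(m), "\n", maxval, "\n", sep = "", file = con)
    write(t(m), file = con, ncolumns = min(ncol(m), 32L))
    path
  }
  paths <- vapply(seq_along(movie$frames), function(i) {
    write_pgm(movie$frames[[i]],
              file.path(dir, sprintf("frame_%02d.pgm", i)))
  }, character(1))
  paths <- c(paths, write_pgm(unclass(movie$masks),
                              file.path(dir, "masks.pgm"), maxval = 2L))
  invisible(paths)
}
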