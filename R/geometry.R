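#' Maze and arena geometry
#'
#' A `maze_geometry` stores named planar polygons (matrices of x,y vertices
#' in cm, maze coordinate frame: origin at the maze centroid, y up) for the
#' coarse regions (`arm1`, `arm2`, `arm3`, `center`), a five-zone variant
#' used by the zone decoder, and the reward-zone polygons at the distal
#' ends of arms 1 and 2.
#'
#' @param regions named list of polygons; assignment ties on shared edges
#'   are broken toward the first-listed region.
#' @param zones5 list of `list(zone =, poly =)` entries; several polygons
#'   may share one zone label.
#' @param reward_zones named list with polygons `arm1`, `arm2`.
#' @param arm_length arm length in cm.
#' @param spouts named list of spout coordinates.
#' @return a `maze_geometry` object.
#' @export
maze_geometry <- function(regions, zones5 = NULL, reward_zones = NULL,
                          arm_length = 30, spouts = NULL) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  for (p in regions) stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 3)
  structure(
    list(regions = regions, zones5 = zones5, reward_zones = reward_zones,
         arm_length = arm_length, spouts = spouts),
    class = "maze_geometry"
  )
}

# rectangle along direction `ang` (radians) from radius r0 to r1, width w
.arm_rect <- function(ang, r0, r1, w) {
  u <- c(cos(ang), sin(ang))
  p <- c(-sin(ang), cos(ang))
  rbind(
    r0 * u + (w / 2) * p,
    r1 * u + (w / 2) * p,
    r1 * u - (w / 2) * p,
    r0 * u - (w / 2) * p
  )
}

#' Default Y-maze geometry
#'
#' Three arms of `arm_length` cm (default 30) at 120 degrees, arm 1
#' pointing up; a hexagonal center joins the arm bases. Reward zones are
#' the distal `reward_len` cm of arms 1 and 2, with the water spouts at the
#' distal arm ends. The five-zone variant splits arms 1 and 2 into
#' proximal/distal halves and pools center with arm 3 into a middle zone,
#' i.e. five positions along the reward-to-reward corridor.
#'
#' @param arm_length cm, default 30.
#' @param arm_width cm.
#' @param center_radius distance from the origin to the arm bases, cm.
#' @param reward_len length of the reward zone at the distal arm end, cm.
#' @export
ymaze_geometry <- function(arm_length = 30, arm_width = 6, center_radius = 5,
                           reward_len = 5) {
  angs <- c(arm1 = pi / 2, arm2 = pi / 2 + 2 * pi / 3, arm3 = pi / 2 - 2 * pi / 3)
  r1 <- center_radius + arm_length
  arms <- lapply(angs, .arm_rect, r0 = center_radius, r1 = r1, w = arm_width)
  hexv <- do.call(rbind, lapply(angs, function(a) {
    u <- c(cos(a), sin(a)); p <- c(-sin(a), cos(a))
    rbind(center_radius * u + (arm_width / 2) * p,
          center_radius * u - (arm_width / 2) * p)
  }))
  hexv <- hexv[order(atan2(hexv[, 2], hexv[, 1])), ]
  regions <- c(arms, list(center = hexv))
  mid <- center_radius + arm_length / 2
  zones5 <- list(
    list(zone = "arm1_distal", poly = .arm_rect(angs[["arm1"]], mid, r1, arm_width)),
    list(zone = "arm1_proximal", poly = .arm_rect(angs[["arm1"]], center_radius, mid, arm_width)),
    list(zone = "middle", poly = hexv),
    list(zone = "middle", poly = arms$arm3),
    list(zone = "arm2_proximal", poly = .arm_rect(angs[["arm2"]], center_radius, mid, arm_width)),
    list(zone = "arm2_distal", poly = .arm_rect(angs[["arm2"]], mid, r1, arm_width))
  )
  reward_zones <- list(
    arm1 = .arm_rect(angs[["arm1"]], r1 - reward_len, r1, arm_width),
    arm2 = .arm_rect(angs[["arm2"]], r1 - reward_len, r1, arm_width)
  )
  spouts <- list(
    arm1 = r1 * c(cos(angs[["arm1"]]), sin(angs[["arm1"]])),
    arm2 = r1 * c(cos(angs[["arm2"]]), sin(angs[["arm2"]]))
  )
  maze_geometry(regions, zones5, reward_zones, arm_length, spouts)
}

#' Default open-field geometry
#'
#' A `side` x `side` cm square arena centred at the origin, with a center
#' zone of half the linear dimension (20 x 20 cm by default) used for
#' anxiety-related center-entry counts.
#'
#' @param side arena side, cm (default 40).
#' @export
openfield_geometry <- function(side = 40) {
  h <- side / 2
  q <- side / 4
  maze_geometry(
    regions = list(
      center = rbind(c(-q, -q), c(q, -q), c(q, q), c(-q, q)),
      border = rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
    ),
    arm_length = side
  )
}

# point-in-polygon with boundary points counted as inside (tolerance eps)
.pip <- function(x, y, poly, eps = 1e-9) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  x <- ifelse(is.finite(x), x, 1e9)
  y <- ifelse(is.finite(y), y, 1e9)
  inside <- mgcv::in.out(bnd, cbind(x, y))
  out <- which(!inside & is.finite(x))
  if (length(out) > 0) {
    for (i in seq_len(nrow(poly))) {
      a <- bnd[i, ]; b <- bnd[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      tproj <- pmin(1, pmax(0, ((x[out] - a[1]) * ab[1] + (y[out] - a[2]) * ab[2]) / len2))
      d2 <- (x[out] - a[1] - tproj * ab[1])^2 + (y[out] - a[2] - tproj * ab[2])^2
      hit <- d2 <= eps^2
      inside[out[hit]] <- TRUE
      out <- out[!hit]
      if (length(out) == 0) break
    }
  }
  inside & is.finite(x)
}

#' @rdname maze_geometry
#' @param geom geometry object.
#' @param path JSON file.
#' @export
write_geometry <- function(geom, path) {
  ser <- function(p) lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
  env <- list(
    format_version = FORMAT_VERSION,
    arm_length = geom$arm_length,
    regions = lapply(geom$regions, ser),
    zones5 = lapply(geom$zones5, function(z) list(zone = z$zone, poly = ser(z$poly))),
    reward_zones = lapply(geom$reward_zones, ser),
    spouts = lapply(geom$spouts, as.numeric)
  )
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname maze_geometry
#' @export
load_geometry <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(env$format_version, FORMAT_VERSION)) {
    rlang::abort("geometry file written by an incompatible format version.")
  }
  de <- function(p) do.call(rbind, lapply(p, function(v) unlist(v)))
  maze_geometry(
    regions = lapply(env$regions, de),
    zones5 = if (length(env$zones5)) {
      lapply(env$zones5, function(z) list(zone = z$zone, poly = de(z$poly)))
    },
    reward_zones = if (length(env$reward_zones)) lapply(env$reward_zones, de),
    arm_length = env$arm_length,
    spouts = if (length(env$spouts)) lapply(env$spouts, unlist)
  )
}
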