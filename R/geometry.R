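#' Half-space-clipped ellipsoid
#'
#' The building block of every candidate defended area: an axis-aligned
#' ellipsoid, optionally intersected with closed half-spaces. A point belongs
#' to the solid iff it lies inside (or on) the ellipsoid and, for every clip,
#' satisfies `normal %*% (point - center) >= offset`. Clips are closed, so
#' boundary points count as inside; this keeps point and ray queries
#' consistent at ray parameter t = 0.
#'
#' Coordinates are head-centered, in cm: +x forward (ventral), +y left,
#' +z up. Semiaxis order is (dorso-ventral, medio-lateral, rostro-caudal).
#'
#' @param center Numeric 3-vector, cm.
#' @param semiaxes Numeric 3-vector of strictly positive semiaxis lengths, cm.
#' @param clips List of clips, each a list with elements `normal` (unit
#'   3-vector) and `offset` (cm). Empty list for an unclipped ellipsoid.
#' @return An object of class `clipped_ellipsoid`.
#' @examples
#' clipped_ellipsoid(c(0, 0, 0), c(9.8, 7.4, 11.3))
#' @export
clipped_ellipsoid <- function(center, semiaxes, clips = list()) {
  center <- as.numeric(center)
  semiaxes <- as.numeric(semiaxes)
  stopifnot(length(center) == 3, length(semiaxes) == 3)
  if (!all(is.finite(center)) || !all(is.finite(semiaxes))) {
    stop("ellipsoid center and semiaxes must be finite", call. = FALSE)
  }
  if (any(semiaxes <= 0)) {
    stop("all semiaxes must be strictly positive", call. = FALSE)
  }
  clips <- lapply(clips, function(cl) {
    normal <- as.numeric(cl$normal)
    offset <- as.numeric(cl$offset)
    stopifnot(length(normal) == 3, length(offset) == 1)
    nrm <- sqrt(sum(normal^2))
    if (abs(nrm - 1) > 1e-9) {
      stop("clip normals must be unit length (|norm - 1| <= 1e-9)", call. = FALSE)
    }
    list(normal = normal, offset = offset)
  })
  structure(
    list(center = center, semiaxes = semiaxes, clips = clips),
    class = "clipped_ellipsoid"
  )
}

#' Canonical defended-area geometries
#'
#' Builds one of the four candidate solids the nervous system is modelled as
#' defending: the whole head (full ellipsoid), the face (forward
#' half-ellipsoid), the upper half of the face (forward-upper
#' quarter-ellipsoid), or the two eyes (a pair of small forward
#' half-ellipsoids on the head surface). Head semiaxes are (9.8, 7.4, 11.3)
#' cm; eye semiaxes are (0.5, 2, 2) cm, from standard head and orbit
#' anthropometry.
#'
#' Eye placement: centers at `(x_e, +/- eye_y, eye_z)` with
#' `x_e = 9.8 * sqrt(1 - (eye_y/7.4)^2 - (eye_z/11.3)^2)` so the eye centers
#' sit on the head-ellipsoid surface; each eye is clipped to its forward half
#' (`x >= x_e`). Defaults put the eyes at eye level (z = 0) with a 6.2 cm
#' interpupillary distance.
#'
#' @param kind One of `"head"`, `"face"`, `"half_face"`, `"eyes"`.
#' @param eye_y Half the interpupillary distance, cm.
#' @param eye_z Height of the eyes above the head-ellipsoid center, cm.
#' @return An object of class `defended_area`: a named list of
#'   `clipped_ellipsoid` components (one for head/face/half_face, two for
#'   eyes).
#' @examples
#' defended_area("face")
#' defended_area("eyes", eye_y = 3.1)
#' @export
defended_area <- function(kind = c("head", "face", "half_face", "eyes"),
                          eye_y = 3.1, eye_z = 0) {
  valid <- c("head", "face", "half_face", "eyes")
  if (length(kind) == 1 && !kind %in% valid) {
    stop(
      "unknown defended-area kind '", kind, "'; valid kinds: ",
      paste(valid, collapse = ", "),
      call. = FALSE
    )
  }
  kind <- match.arg(kind)
  head_axes <- c(9.8, 7.4, 11.3)
  forward <- list(normal = c(1, 0, 0), offset = 0)
  upward <- list(normal = c(0, 0, 1), offset = 0)
  components <- switch(kind,
    head = list(clipped_ellipsoid(c(0, 0, 0), head_axes)),
    face = list(clipped_ellipsoid(c(0, 0, 0), head_axes, list(forward))),
    half_face = list(
      clipped_ellipsoid(c(0, 0, 0), head_axes, list(forward, upward))
    ),
    eyes = {
      frac <- 1 - (eye_y / head_axes[2])^2 - (eye_z / head_axes[3])^2
      if (frac <= 0) {
        stop("eye offsets place the eyes off the head surface", call. = FALSE)
      }
      x_e <- head_axes[1] * sqrt(frac)
      eye_axes <- c(0.5, 2, 2)
      lapply(c(1, -1), function(side) {
        clipped_ellipsoid(
          c(x_e, side * eye_y, eye_z), eye_axes,
          list(list(normal = c(1, 0, 0), offset = 0))
        )
      })
    }
  )
  structure(list(name = kind, components = components), class = "defended_area")
}

#' @export
print.defended_area <- function(x, ...) {
  cat("<defended_area> ", x$name, ": ", length(x$components),
    " clipped-ellipsoid component(s)\n",
    sep = ""
  )
  for (comp in x$components) {
    cat(
      "  center (", paste(format(comp$center), collapse = ", "),
      ") cm; semiaxes (", paste(format(comp$semiaxes), collapse = ", "),
      ") cm; ", length(comp$clips), " clip(s)\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Wrap arbitrary components into a defended area
#'
#' Lets users define custom solids (for example a sphere, for analytic
#' cross-checks) that work with every query, field, and fitting function.
#'
#' @param components List of [clipped_ellipsoid()] objects.
#' @param name Label for the area.
#' @return A `defended_area`.
#' @export
custom_area <- function(components, name = "custom") {
  stopifnot(length(components) >= 1)
  ok <- vapply(components, inherits, logical(1), "clipped_ellipsoid")
  if (!all(ok)) stop("all components must be clipped_ellipsoid objects", call. = FALSE)
  structure(list(name = name, components = components), class = "defended_area")
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- cbind(points$x, points$y, points$z)
  } else if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(as.numeric(points), ncol = 3)
  }
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}

component_contains <- function(comp, pts) {
  rel <- sweep(pts, 2, comp$center, "-")
  scl <- sweep(rel, 2, comp$semiaxes, "/")
  inside <- rowSums(scl^2) <= 1
  for (cl in comp$clips) {
    inside <- inside & (rel %*% cl$normal >= cl$offset)
  }
  as.vector(inside)
}

#' Point-membership query
#'
#' @param area A [defended_area()].
#' @param points A 3-vector, an n x 3 matrix, or a data frame with columns
#'   `x`, `y`, `z` (cm).
#' @return Logical vector: `TRUE` where the point lies inside or on the
#'   boundary of any component.
#' @examples
#' area_contains(defended_area("head"), c(0, 0, 0))
#' @export
area_contains <- function(area, points) {
  stopifnot(inherits(area, "defended_area"))
  pts <- as_point_matrix(points)
  inside <- rep(FALSE, nrow(pts))
  for (comp in area$components) {
    inside <- inside | component_contains(comp, pts)
  }
  inside
}

# Hit test of half-lines {origin + t*dir, t >= 0} against one component:
# the quadratic ray-ellipsoid parameter interval intersected with each clip's
# half-line interval. Vectorized over rays (dirs is n x 3).
component_ray_hits <- function(comp, origin, dirs) {
  u <- (origin - comp$center) / comp$semiaxes
  v <- sweep(dirs, 2, comp$semiaxes, "/")
  a <- rowSums(v^2)
  b <- 2 * as.vector(v %*% u)
  cc <- sum(u^2) - 1
  disc <- b^2 - 4 * a * cc
  has <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  lo <- pmax((-b - sq) / (2 * a), 0)
  hi <- (-b + sq) / (2 * a)
  for (cl in comp$clips) {
    # n.(o + t d - c) >= offset  <=>  g + t*h >= offset
    g <- sum(cl$normal * (origin - comp$center))
    h <- as.vector(dirs %*% cl$normal)
    tcrit <- (cl$offset - g) / h
    pos <- h > 0
    neg <- h < 0
    zero <- h == 0
    lo <- ifelse(pos, pmax(lo, tcrit), lo)
    hi <- ifelse(neg, pmin(hi, tcrit), hi)
    has <- has & !(zero & g < cl$offset)
  }
  has & (lo <= hi) & (hi >= 0)
}

#' Ray-solid intersection query
#'
#' Tests whether half-lines starting at `origin` intersect the defended
#' area. Directions need not be normalized: only the line matters. Rays
#' originating inside the solid hit (t = 0 is admissible).
#'
#' @param area A [defended_area()].
#' @param origin Numeric 3-vector, cm.
#' @param directions A 3-vector or n x 3 matrix of nonzero direction vectors.
#' @return Logical vector of length n.
#' @examples
#' ray_hits(defended_area("head"), c(20, 0, 0), c(-1, 0, 0))
#' @export
ray_hits <- function(area, origin, directions) {
  stopifnot(inherits(area, "defended_area"))
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3)
  dirs <- as_point_matrix(directions)
  if (any(rowSums(dirs^2) == 0)) {
    stop("direction vectors must be nonzero", call. = FALSE)
  }
  hit <- rep(FALSE, nrow(dirs))
  for (comp in area$components) {
    hit <- hit | component_ray_hits(comp, origin, dirs)
  }
  hit
}

#' Serialize and deserialize defended areas
#'
#' Round-trips a geometry through a plain JSON document (name, per-component
#' center, semiaxes, and clips), so custom defended areas can be stored
#' alongside results and shared between runs.
#'
#' @param area A `defended_area`.
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `area_to_json()`: the JSON string (invisibly, when written to a
#'   file). `area_from_json()`: a `defended_area`.
#' @export
area_to_json <- function(area, path = NULL) {
  stopifnot(inherits(area, "defended_area"))
  doc <- list(
    name = area$name,
    components = lapply(area$components, function(comp) {
      list(
        center = comp$center,
        semiaxes = comp$semiaxes,
        clips = lapply(comp$clips, function(cl) {
          list(normal = cl$normal, offset = cl$offset)
        })
      )
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(as.character(json))
  }
  writeLines(json, path)
  invisible(as.character(json))
}

#' @rdname area_to_json
#' @param json A JSON string or path to a JSON file produced by
#'   [area_to_json()].
#' @export
area_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  components <- lapply(doc$components, function(comp) {
    clipped_ellipsoid(
      unlist(comp$center), unlist(comp$semiaxes),
      lapply(comp$clips, function(cl) {
        list(normal = unlist(cl$normal), offset = cl$offset)
      })
    )
  })
  custom_area(components, name = doc$name)
}
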