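#' Micropattern specification
#'
#' Geometry of the adhesive micropattern.  The default two-state pattern has
#' two 38 x 38 um basins joined by a 10 x 35 um bridge (10 um wide in y,
#' 35 um long in x), for a 111 x 38 um bounding box; the rectangle is
#' 111 x 38 um; \code{free2d} is a fully adhesive plane; \code{composite}
#' takes an explicit list of simple polygons whose union is the pattern.
#'
#' @param kind one of \code{"two_state"}, \code{"rectangle"},
#'   \code{"free2d"}, \code{"composite"}.
#' @param basin basin width and height (um), two-state only.
#' @param bridge bridge width (y) and length (x) in um, two-state only.
#' @param rect rectangle width (x) and height (y) in um.
#' @param polygons list of n x 2 vertex matrices (um), composite only.
#' @param w_chi smoothing width of the pattern edge (um); the chi field is
#'   logistic in signed distance with this scale.
#' @return an object of class \code{pf_pattern}.
#' @export
pattern_spec <- function(kind = c("two_state", "rectangle", "free2d", "composite"),
                         basin = c(38, 38), bridge = c(10, 35),
                         rect = c(111, 38), polygons = NULL, w_chi = 1.2) {
  kind <- match.arg(kind)
  if (kind == "composite") {
    if (is.null(polygons) || !length(polygons))
      stop("composite pattern needs a non-empty 'polygons' list")
    polygons <- lapply(polygons, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2 || nrow(p) < 3) stop("each polygon needs >= 3 (x, y) vertices")
      if (is_self_intersecting(p)) stop("composite polygons must be simple (non-self-intersecting)")
      p
    })
  }
  structure(list(kind = kind, basin = basin, bridge = bridge, rect = rect,
                 polygons = polygons, w_chi = w_chi),
            class = "pf_pattern")
}

#' @export
print.pf_pattern <- function(x, ...) {
  bb <- pattern_bbox(x)
  cat(sprintf("pf_pattern '%s', bounding box %g x %g um, w_chi = %g um\n",
              x$kind, bb[1], bb[2], x$w_chi))
  invisible(x)
}

#' Polygon representation of a pattern
#'
#' @param spec a \code{pf_pattern}.
#' @return list of vertex matrices (empty for \code{free2d}).
#' @export
pattern_polygons <- function(spec) {
  switch(spec$kind,
    free2d = list(),
    rectangle = {
      hx <- spec$rect[1] / 2; hy <- spec$rect[2] / 2
      list(cbind(c(-hx, hx, hx, -hx), c(-hy, -hy, hy, hy)))
    },
    two_state = {
      bw <- spec$basin[1]; bh <- spec$basin[2]
      ww <- spec$bridge[1] / 2          # half bridge width (y)
      bl <- spec$bridge[2]              # bridge length (x)
      hx <- bw + bl / 2                 # half total extent in x
      xb <- bl / 2                      # bridge half-length
      hy <- bh / 2
      list(cbind(
        c(-hx, -xb, -xb,  xb,  xb,  hx,  hx,  xb,  xb, -xb, -xb, -hx),
        c(-hy, -hy, -ww, -ww, -hy, -hy,  hy,  hy,  ww,  ww,  hy,  hy)))
    },
    composite = spec$polygons)
}

#' Bounding box (width, height) of a pattern
#'
#' @param spec a \code{pf_pattern}.
#' @return numeric (width, height) in um; \code{free2d} returns \code{c(Inf, Inf)}.
#' @export
pattern_bbox <- function(spec) {
  polys <- pattern_polygons(spec)
  if (!length(polys)) return(c(Inf, Inf))
  xs <- unlist(lapply(polys, function(p) range(p[, 1])))
  ys <- unlist(lapply(polys, function(p) range(p[, 2])))
  c(diff(range(xs)), diff(range(ys)))
}

# grid large enough to hold the pattern with the requested padding; free2d
# gets a square domain sized for an unconfined cell.
pattern_grid <- function(spec, params) {
  polys <- pattern_polygons(spec)
  if (length(polys)) {
    xs <- range(unlist(lapply(polys, function(p) p[, 1])))
    ys <- range(unlist(lapply(polys, function(p) p[, 2])))
  } else {
    r <- 3 * params$R0
    xs <- c(-r, r); ys <- c(-r, r)
  }
  pad <- max(params$pad, 2 * params$lambda)
  dx <- params$dx
  x0 <- floor((xs[1] - pad) / dx) * dx
  x1 <- ceiling((xs[2] + pad) / dx) * dx
  y0 <- floor((ys[1] - pad) / dx) * dx
  y1 <- ceiling((ys[2] + pad) / dx) * dx
  list(nx = round((x1 - x0) / dx) + 1L, ny = round((y1 - y0) / dx) + 1L,
       dx = dx, origin = c(x0, y0))
}

#' Build the static micropattern field chi
#'
#' chi is 0 well inside the adhesive pattern and 1 well outside,
#' transitioning as a logistic function of signed distance to the pattern
#' boundary with width \code{w_chi} (so chi = 1/2 on the boundary).
#'
#' @param spec a \code{pf_pattern}.
#' @param grid either \code{NULL} (a grid is derived from the pattern and
#'   \code{params}), a \code{pf_field} whose grid is reused, or a list with
#'   \code{nx}, \code{ny}, \code{dx}, \code{origin}.
#' @param params a \code{pf_params} object (grid spacing and padding).
#' @return a \code{pf_field} with values in [0, 1].
#' @export
build_pattern <- function(spec, grid = NULL, params = model_params()) {
  if (is.null(grid)) grid <- pattern_grid(spec, params)
  if (inherits(grid, "pf_field"))
    grid <- list(nx = nrow(grid$values), ny = ncol(grid$values),
                 dx = grid$dx, origin = grid$origin)
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dx
  polys <- pattern_polygons(spec)
  if (!length(polys)) {
    return(scalar_field(matrix(0, grid$nx, grid$ny), grid$dx, grid$origin))
  }
  bbx <- range(unlist(lapply(polys, function(p) p[, 1])))
  bby <- range(unlist(lapply(polys, function(p) p[, 2])))
  if (bbx[1] < xs[1] || bbx[2] > xs[length(xs)] ||
      bby[1] < ys[1] || bby[2] > ys[length(ys)])
    stop("micropattern does not fit inside the supplied grid")
  pts <- cbind(rep(xs, times = grid$ny), rep(ys, each = grid$nx))
  d <- signed_distance(pts, polys)
  chi <- matrix(stats::plogis(d / spec$w_chi), grid$nx, grid$ny)
  scalar_field(chi, grid$dx, grid$origin)
}

#' Signed distance to a union of polygons
#'
#' Negative inside the union, positive outside, zero on the boundary.
#'
#' @param pts n x 2 matrix of query points.
#' @param polys list of vertex matrices.
#' @return numeric vector of signed distances (um).
#' @export
signed_distance <- function(pts, polys) {
  pts <- as.matrix(pts)
  d <- rep(Inf, nrow(pts))
  inside <- rep(FALSE, nrow(pts))
  for (p in polys) {
    d <- pmin(d, dist_to_polygon(pts, p))
    inside <- inside | point_in_polygon(pts, p)
  }
  ifelse(inside, -d, d)
}

# unsigned distance from points to the edges of one polygon
dist_to_polygon <- function(pts, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# even-odd rule point-in-polygon, vectorised over points
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    xi <- poly[i, 1]; xj <- poly[j, 1]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2]))
    if (any(crosses)) {
      xint <- xi + (pts[crosses, 2] - yi) / (yj - yi) * (xj - xi)
      inside[crosses] <- xor(inside[crosses], pts[crosses, 1] < xint)
    }
    j <- i
  }
  inside
}

# O(n^2) segment-crossing test, adequate for config-sized polygons
is_self_intersecting <- function(poly) {
  n <- nrow(poly)
  seg <- function(k) rbind(poly[k, ], poly[if (k == n) 1 else k + 1, ])
  ccw <- function(a, b, c) (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  intersects <- function(s1, s2) {
    ccw(s1[1, ], s2[1, ], s2[2, ]) != ccw(s1[2, ], s2[1, ], s2[2, ]) &&
      ccw(s1[1, ], s1[2, ], s2[1, ]) != ccw(s1[1, ], s1[2, ], s2[2, ])
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through the wrap-around
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

#' Areas of the left and right basins of a pattern
#'
#' Polygon areas of the parts of the pattern at x < -x_split and
#' x > +x_split, used as the weights of the occupancy statistic.  For the
#' built-in two-state pattern these are the two square basins.  For
#' composite patterns the polygons are assigned to sides by the sign of
#' their centroid x.
#'
#' @param spec a \code{pf_pattern}.
#' @param x_split boundary between basins and bridge (um); defaults to the
#'   bridge half-length for the two-state pattern, 0 otherwise.
#' @return list with \code{A_left}, \code{A_right} (um^2).
#' @export
basin_areas <- function(spec, x_split = NULL) {
  if (spec$kind == "two_state") {
    A <- spec$basin[1] * spec$basin[2]
    return(list(A_left = A, A_right = A))
  }
  if (spec$kind == "rectangle") {
    if (is.null(x_split)) x_split <- 0
    hx <- spec$rect[1] / 2
    A <- (hx - x_split) * spec$rect[2]
    return(list(A_left = A, A_right = A))
  }
  if (spec$kind == "composite") {
    al <- 0; ar <- 0
    for (p in spec$polygons) {
      cx <- mean(p[, 1])
      if (cx < 0) al <- al + polygon_area(p)
      else if (cx > 0) ar <- ar + polygon_area(p)
    }
    return(list(A_left = al, A_right = ar))
  }
  stop("basin areas are not defined for pattern kind '", spec$kind, "'")
}
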