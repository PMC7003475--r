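#' Create a tapering 1D vessel segment
#'
#' A segment is the atomic unit of a coronary tree: a straight 1D vessel with
#' a reference (zero transmural pressure) cross-sectional area profile
#' \eqn{A_0(x)} sampled uniformly from the proximal to the distal end. The
#' reference diameter profile \eqn{D_0(x) = 2\sqrt{A_0/\pi}} is derived on
#' demand; it drives both the empirical wave speed and the wall viscosity.
#'
#' Either `area_profile` is given explicitly (length `n_points`), or a
#' proximal `diameter` plus a `taper` factor (distal/proximal diameter ratio)
#' builds a linearly tapering diameter profile.
#'
#' @param id segment identifier (character)
#' @param length segment length, cm
#' @param diameter proximal reference diameter, cm (ignored if `area_profile`
#'   given)
#' @param taper distal/proximal diameter ratio (default 1, no taper)
#' @param area_profile optional explicit A0(x) samples, cm2
#' @param n_points number of axial samples; default from `dx_target`
#' @param dx_target target axial spacing used to pick `n_points`, cm
#' @return object of class `vessel_segment`
#' @export
vessel_segment <- function(id, length, diameter = NULL, taper = 1,
                           area_profile = NULL, n_points = NULL,
                           dx_target = 0.05) {
  stopifnot(is.character(id), nchar(id) > 0)
  if (!is.numeric(length) || length <= 0)
    stop("segment '", id, "': length must be > 0")
  if (is.null(n_points))
    n_points <- max(2L, as.integer(round(length / dx_target)) + 1L)
  if (is.null(area_profile)) {
    if (is.null(diameter) || diameter <= 0)
      stop("segment '", id, "': need a positive diameter or an area profile")
    if (taper <= 0) stop("segment '", id, "': taper must be > 0")
    d <- seq(diameter, diameter * taper, length.out = n_points)
    area_profile <- pi * (d / 2)^2
  } else {
    if (length(area_profile) != n_points)
      n_points <- length(area_profile)
    if (any(!is.finite(area_profile)) || any(area_profile <= 0))
      stop("segment '", id, "': all reference areas must be finite and > 0")
  }
  if (n_points < 2) stop("segment '", id, "': n_points must be >= 2")
  structure(list(id = id, length = length, n_points = as.integer(n_points),
                 area_profile = as.numeric(area_profile)),
            class = "vessel_segment")
}

#' Reference diameter profile of a segment
#' @param segment a `vessel_segment`
#' @return D0(x) in cm, same sampling as the area profile
#' @export
segment_diameters <- function(segment) 2 * sqrt(segment$area_profile / pi)

#' @export
print.vessel_segment <- function(x, ...) {
  d <- segment_diameters(x)
  cat(sprintf("<vessel_segment '%s'> L = %.3g cm, D0 = %.3g -> %.3g cm (%d pts)\n",
              x$id, x$length, d[1], d[length(d)], x$n_points))
  invisible(x)
}

#' Assemble a validated coronary tree network
#'
#' Builds a rooted tree from a list of segments and a parent -> children
#' connectivity map. The root is the unique segment that never appears as a
#' child; terminals are segments with no children. Cycles, orphans and
#' multiple roots are rejected with errors naming the offending segment.
#'
#' @param segments list of `vessel_segment` objects
#' @param connectivity named list: parent segment id -> character vector of
#'   child segment ids (order preserved). May be empty for a single segment.
#' @param side which coronary ostium the tree hangs off: "left" or "right";
#'   selects the inflow waveform and the ventricular pressure source used by
#'   the terminal beds
#' @return object of class `coronary_network`
#' @export
build_network <- function(segments, connectivity = list(), side = c("left", "right")) {
  side <- match.arg(side)
  ids <- unname(vapply(segments, function(s) s$id, character(1)))
  if (anyDuplicated(ids))
    stop("duplicate segment id: '", ids[duplicated(ids)][1], "'")
  names(segments) <- ids
  connectivity <- lapply(connectivity, as.character)

  for (p in names(connectivity)) {
    if (!p %in% ids) stop("connectivity parent '", p, "' is not a segment")
    for (ch in connectivity[[p]])
      if (!ch %in% ids) stop("connectivity child '", ch, "' is not a segment")
  }
  children <- connectivity[lengths(connectivity) > 0]
  all_children <- unlist(children, use.names = FALSE)
  if (anyDuplicated(all_children))
    stop("segment '", all_children[duplicated(all_children)][1],
         "' has multiple parents (cycle or reconvergence)")
  roots <- setdiff(ids, all_children)
  if (length(roots) == 0)
    stop("cycle detected: every segment is someone's child")
  if (length(roots) > 1)
    stop("multiple roots: ", paste0("'", roots, "'", collapse = ", "))
  root <- roots

  # walk from the root; unreachable segments are orphans, revisits are cycles
  visited <- character(0)
  stack <- root
  while (length(stack)) {
    s <- stack[[1]]; stack <- stack[-1]
    if (s %in% visited) stop("cycle detected at segment '", s, "'")
    visited <- c(visited, s)
    stack <- c(children[[s]], stack)
  }
  orphans <- setdiff(ids, visited)
  if (length(orphans))
    stop("orphan segment(s) not reachable from root: ",
         paste0("'", orphans, "'", collapse = ", "))

  parent <- character(0)
  for (p in names(children)) for (ch in children[[p]]) parent[ch] <- p
  terminals <- ids[!ids %in% names(children)]

  structure(list(segments = segments, children = children, parent = parent,
                 root = root, terminals = terminals, side = side,
                 metadata = list()),
            class = "coronary_network")
}

#' @export
print.coronary_network <- function(x, ...) {
  cat(sprintf("<coronary_network> %d segments, root '%s' (%s side), %d terminals\n",
              length(x$segments), x$root, x$side, length(x$terminals)))
  invisible(x)
}

#' Topologically ordered segment ids (root first)
#' @param network a `coronary_network`
#' @return character vector
#' @export
network_order <- function(network) {
  out <- character(0); stack <- network$root
  while (length(stack)) {
    s <- stack[[1]]; stack <- stack[-1]
    out <- c(out, s)
    stack <- c(network$children[[s]], stack)
  }
  out
}

#' Superimpose a stenosis on a segment's reference area profile
#'
#' The reference area is multiplied pointwise by a smooth occlusion profile
#' that reaches `1 - area_reduction` at the throat and 1 at the edges of the
#' stenosed window; areas outside the window are untouched. The cosine shape
#' is C1-continuous (focal lesions); the trapezoid has a flat throat occupying
#' half the window (diffuse disease). Stacking several stenoses on one
#' segment composes multiplicatively.
#'
#' @param network a `coronary_network`
#' @param segment_id id of the segment carrying the lesion
#' @param center_fraction throat position as a fraction of segment length,
#'   in (0, 1)
#' @param stenosed_length axial extent of the lesion, cm
#' @param area_reduction fractional area reduction at the throat, in [0, 1)
#' @param shape "cosine" (default) or "trapezoid"
#' @return the network with the modified segment
#' @export
apply_stenosis <- function(network, segment_id, center_fraction,
                           stenosed_length, area_reduction,
                           shape = c("cosine", "trapezoid")) {
  shape <- match.arg(shape)
  if (!segment_id %in% names(network$segments))
    stop("no segment '", segment_id, "' in network")
  seg <- network$segments[[segment_id]]
  if (!(center_fraction > 0 && center_fraction < 1))
    stop("center_fraction must be in (0,1)")
  if (area_reduction < 0 || area_reduction >= 1)
    stop("area_reduction must be in [0,1)")
  if (stenosed_length <= 0 || stenosed_length > seg$length)
    stop("stenosed_length must be in (0, segment length]")
  xc <- center_fraction * seg$length
  if (xc - stenosed_length / 2 < -1e-9 ||
      xc + stenosed_length / 2 > seg$length + 1e-9)
    stop("stenosed window [", signif(xc - stenosed_length / 2, 4), ", ",
         signif(xc + stenosed_length / 2, 4), "] exceeds segment '",
         segment_id, "' bounds [0, ", seg$length, "]")
  x <- seq(0, seg$length, length.out = seg$n_points)
  f <- stenosis_profile(x, xc, stenosed_length, area_reduction, shape)
  seg$area_profile <- seg$area_profile * f
  network$segments[[segment_id]] <- seg
  network
}

# occlusion multiplier f(x) in (0,1]; vectorized over x
stenosis_profile <- function(x, xc, w, r, shape) {
  u <- (x - xc) / w            # -0.5 .. 0.5 inside the window
  f <- rep(1, length(x))
  inside <- abs(u) <= 0.5
  if (shape == "cosine") {
    f[inside] <- 1 - r * 0.5 * (1 + cos(2 * pi * u[inside]))
  } else {
    # trapezoid: linear ramps over the outer quarters, flat throat
    ui <- abs(u[inside])
    ramp <- pmin(1, pmax(0, (0.5 - ui) / 0.25))
    f[inside] <- 1 - r * ramp
  }
  f
}

#' Generate a synthetic coronary tree
#'
#' Stand-in for segmented CCTA centreline output: a rooted binary tree of
#' tapering segments. Daughter proximal diameters obey the generalized Murray
#' relation \eqn{d_{parent}^\gamma = \sum_k d_{child,k}^\gamma} exactly at
#' every junction (applied at the parent's distal diameter), with a random
#' asymmetry ratio. Segment lengths and taper are drawn from uniform ranges
#' recorded in the returned metadata. Deterministic for a fixed seed.
#'
#' @param seed integer RNG seed
#' @param n_generations number of generations (1 = single root segment)
#' @param root_diameter proximal diameter of the root, cm (0.15 to 0.6)
#' @param gamma Murray exponent (default 2.27)
#' @param length_range root-generation segment length range, cm; lengths
#'   shrink by `length_decay` per generation (clamped at 0.5 cm)
#' @param length_decay per-generation length shrink factor
#' @param asymmetry_range range of the daughter diameter ratio d2/d1
#' @param taper_range range of the distal/proximal diameter taper per segment
#' @param min_diameter branches thinner than this become terminals, cm
#' @param side "left" or "right"
#' @param dx_target axial sampling target, cm
#' @return a `coronary_network` with generation metadata
#' @export
generate_synthetic_tree <- function(seed, n_generations = 4, root_diameter = 0.35,
                                    gamma = 2.27, length_range = c(1, 8),
                                    length_decay = 0.72,
                                    asymmetry_range = c(0.7, 1.0),
                                    taper_range = c(0.85, 1.0),
                                    min_diameter = 0.1,
                                    side = "left", dx_target = 0.05) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (root_diameter < 0.15 || root_diameter > 0.6)
    stop("root_diameter must be in [0.15, 0.6] cm")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  segs <- list(); conn <- list(); counter <- 0
  new_id <- function() { counter <<- counter + 1; sprintf("s%02d", counter) }

  grow <- function(d_prox, gen) {
    id <- new_id()
    L <- max(0.5, stats::runif(1, length_range[1], length_range[2]) *
               length_decay^(gen - 1))
    tp <- stats::runif(1, taper_range[1], taper_range[2])
    segs[[id]] <<- vessel_segment(id, L, diameter = d_prox, taper = tp,
                                  dx_target = dx_target)
    d_dist <- d_prox * tp
    if (gen < n_generations && d_dist >= min_diameter) {
      xi <- stats::runif(1, asymmetry_range[1], asymmetry_range[2])
      d1 <- d_dist / (1 + xi^gamma)^(1 / gamma)
      d2 <- xi * d1
      if (min(d1, d2) >= min_diameter / 2) {
        kids <- c(grow(d1, gen + 1), grow(d2, gen + 1))
        conn[[id]] <<- kids
      }
    }
    id
  }
  grow(root_diameter, 1)
  net <- build_network(segs, conn, side = side)
  net$metadata <- list(generator = "generate_synthetic_tree", seed = seed,
                       n_generations = n_generations, gamma = gamma,
                       root_diameter = root_diameter,
                       length_range = length_range, length_decay = length_decay,
                       asymmetry_range = asymmetry_range,
                       taper_range = taper_range, min_diameter = min_diameter)
  net
}

NETWORK_SCHEMA <- "coroflow-network-1"

#' Read and write network files
#'
#' Networks are stored as JSON with top-level keys `schema`, `side`,
#' `segments` (id, length_cm, n_points, area_profile_cm2), `junctions`
#' (parent id -> ordered child ids) and `metadata`. `read_network` rejects
#' unknown schema versions; `read_network(write_network(net))` is an
#' identity.
#'
#' @param network a `coronary_network`
#' @param path file path
#' @return `read_network` returns a `coronary_network`;
#'   `write_network` returns `path` invisibly
#' @export
write_network <- function(network, path) {
  obj <- list(
    schema = NETWORK_SCHEMA,
    side = network$side,
    root = network$root,
    segments = lapply(unname(network$segments), function(s)
      list(id = s$id, length_cm = s$length, n_points = s$n_points,
           area_profile_cm2 = s$area_profile)),
    junctions = network$children,
    metadata = network$metadata)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed network file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, NETWORK_SCHEMA))
    stop("unknown network schema version: ",
         if (is.null(obj$schema)) "<missing>" else obj$schema)
  segs <- lapply(obj$segments, function(s) {
    for (f in c("id", "length_cm", "n_points", "area_profile_cm2"))
      if (is.null(s[[f]]))
        stop("segment entry missing field '", f, "' in '", path, "'")
    vessel_segment(s$id, s$length_cm,
                   area_profile = as.numeric(unlist(s$area_profile_cm2)),
                   n_points = s$n_points)
  })
  conn <- lapply(obj$junctions, function(ch) as.character(unlist(ch)))
  net <- build_network(segs, conn, side = obj$side)
  net$metadata <- obj$metadata
  net
}
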