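# Parametric coronary tree geometry: vessel segments with sampled diameter
# profiles, rooted-tree topology, the idealized LAD emulator, and concentric
# stenosis insertion.

#' Create a vessel segment
#'
#' A segment is a straight axisymmetric conduit parameterized by arclength
#' `s` in \[0, length\] (mm) with a piecewise-linear diameter profile `d(s)`
#' (mm) stored as sampled `(s, d)` pairs.
#'
#' @param id character token identifying the segment.
#' @param length segment length in mm (> 0).
#' @param profile two-column numeric matrix of `(s_mm, d_mm)` samples with
#'   strictly increasing `s`, first sample at `s = 0`, last at `s = length`,
#'   all diameters > 0. A length-2 numeric vector `c(d0, d1)` is accepted as
#'   shorthand for end-point diameters.
#' @param role `"trunk"` or `"branch"`.
#' @return An object of class `vessel_segment`.
#' @examples
#' vessel_segment("tube", 10, c(3, 3), role = "branch")
#' @export
vessel_segment <- function(id, length, profile, role = c("branch", "trunk")) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("segment id must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(length) || length <= 0) {
    stop(sprintf("segment '%s': length must be > 0", id), call. = FALSE)
  }
  if (is.numeric(profile) && is.null(dim(profile)) && base::length(profile) == 2L) {
    profile <- cbind(c(0, length), profile)
  }
  profile <- as.matrix(profile)
  if (ncol(profile) != 2L || nrow(profile) < 2L) {
    stop(sprintf("segment '%s': profile must have >= 2 rows of (s, d)", id),
         call. = FALSE)
  }
  colnames(profile) <- c("s_mm", "d_mm")
  s <- profile[, 1L]; d <- profile[, 2L]
  if (any(diff(s) <= 0)) {
    stop(sprintf("segment '%s': profile s-samples must be strictly increasing", id),
         call. = FALSE)
  }
  if (abs(s[1L]) > 1e-9 || abs(s[base::length(s)] - length) > 1e-9) {
    stop(sprintf("segment '%s': profile must span s = 0 to s = length", id),
         call. = FALSE)
  }
  if (any(d <= 0)) {
    stop(sprintf("segment '%s': all sampled diameters must be > 0", id),
         call. = FALSE)
  }
  structure(list(id = id, role = role, length_mm = as.numeric(length),
                 profile = profile),
            class = "vessel_segment")
}

#' Diameter of a segment at given arclengths
#'
#' Linear interpolation of the sampled diameter profile.
#'
#' @param segment a [vessel_segment()].
#' @param s arclength(s) in mm, within \[0, length\].
#' @return Numeric vector of diameters in mm.
#' @export
segment_diameter <- function(segment, s) {
  if (any(s < -1e-9 | s > segment$length_mm + 1e-9)) {
    stop(sprintf("arclength outside segment '%s' [0, %g]",
                 segment$id, segment$length_mm), call. = FALSE)
  }
  approx(segment$profile[, 1L], segment$profile[, 2L], xout = s, rule = 2)$y
}

#' Assemble a coronary tree
#'
#' A rooted tree of vessel segments. Children attach to a parent segment at a
#' given arclength on the parent; every segment whose distal end has no
#' continuation is an outlet (so the trunk's distal end is itself an outlet).
#'
#' @param segments list of [vessel_segment()] objects.
#' @param junctions data.frame with columns `parent`, `s_mm`, `child`; one row
#'   per attachment. May have zero rows for a single-tube tree.
#' @param inlet id of the root (inlet) segment.
#' @param metadata optional named list (e.g. `locations`, stenosis record).
#' @return An object of class `coronary_tree` with elements `segments`
#'   (named list), `junctions`, `inlet`, `outlets`, `metadata`, `version`.
#' @export
coronary_tree <- function(segments, junctions = NULL, inlet, metadata = list()) {
  ids <- vapply(segments, function(x) x$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate segment ids", call. = FALSE)
  names(segments) <- ids
  if (is.null(junctions) || NROW(junctions) == 0L) {
    junctions <- data.frame(parent = character(), s_mm = numeric(),
                            child = character(), stringsAsFactors = FALSE)
  }
  junctions <- as.data.frame(junctions, stringsAsFactors = FALSE)
  names(junctions) <- c("parent", "s_mm", "child")
  tree <- structure(list(segments = segments, junctions = junctions,
                         inlet = inlet, outlets = character(),
                         metadata = metadata, version = "1.0"),
                    class = "coronary_tree")
  tree$outlets <- compute_outlets(tree)
  validate_tree(tree)
  tree
}

compute_outlets <- function(tree) {
  # a segment is an outlet unless a child attaches at (numerically) its far end
  ids <- names(tree$segments)
  continued <- vapply(ids, function(id) {
    seg <- tree$segments[[id]]
    j <- tree$junctions[tree$junctions$parent == id, , drop = FALSE]
    any(abs(j$s_mm - seg$length_mm) < 1e-9)
  }, logical(1))
  ids[!continued]
}

#' Validate coronary-tree invariants
#'
#' Checks that the topology is a rooted tree (acyclic, single inlet, every
#' non-root segment attached exactly once), that each attachment arclength
#' lies within its parent, and that every segment profile is well formed.
#' Called by all constructors; exported for use after manual edits.
#'
#' @param tree a [coronary_tree()].
#' @return The tree, invisibly; errors describe the first violation found.
#' @export
validate_tree <- function(tree) {
  ids <- names(tree$segments)
  if (!(tree$inlet %in% ids)) {
    stop(sprintf("inlet segment '%s' not found", tree$inlet), call. = FALSE)
  }
  j <- tree$junctions
  bad <- setdiff(unique(c(j$parent, j$child)), ids)
  if (length(bad)) {
    stop(sprintf("junction references unknown segment '%s'", bad[1L]),
         call. = FALSE)
  }
  if (anyDuplicated(j$child)) {
    stop("a segment is attached to more than one parent (not a tree)",
         call. = FALSE)
  }
  if (tree$inlet %in% j$child) {
    stop("inlet segment cannot be a junction child", call. = FALSE)
  }
  orphans <- setdiff(ids, c(tree$inlet, j$child))
  if (length(orphans)) {
    stop(sprintf("segment '%s' is not connected to the tree", orphans[1L]),
         call. = FALSE)
  }
  for (k in seq_len(nrow(j))) {
    plen <- tree$segments[[j$parent[k]]]$length_mm
    if (j$s_mm[k] < -1e-9 || j$s_mm[k] > plen + 1e-9) {
      stop(sprintf("junction '%s'->'%s': attachment s = %g outside parent [0, %g]",
                   j$parent[k], j$child[k], j$s_mm[k], plen), call. = FALSE)
    }
  }
  # acyclicity: walk from the inlet; every segment must be reached exactly once
  seen <- character()
  stack <- tree$inlet
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    if (cur %in% seen) stop("cycle detected in junction topology", call. = FALSE)
    seen <- c(seen, cur)
    stack <- c(stack, j$child[j$parent == cur])
  }
  if (length(seen) != length(ids)) {
    stop("cycle detected in junction topology", call. = FALSE)
  }
  invisible(tree)
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("<coronary_tree> %d segment(s), %d junction(s), %d outlet(s)\n",
              length(x$segments), nrow(x$junctions), length(x$outlets)))
  trunk <- x$segments[[x$inlet]]
  cat(sprintf("  inlet '%s' (%s): L = %g mm, d = %.2f -> %.2f mm\n",
              trunk$id, trunk$role, trunk$length_mm,
              trunk$profile[1, 2], trunk$profile[nrow(trunk$profile), 2]))
  if (!is.null(x$metadata$stenosis)) {
    st <- x$metadata$stenosis
    cat(sprintf("  stenosis: DS = %.0f%%, length %g mm, centre s = %g mm (%s)\n",
                100 * st$ds, st$length_mm, st$center_s_mm, st$shape))
  }
  if (!is.null(x$metadata$locations)) {
    loc <- unlist(x$metadata$locations)
    cat("  locations:", paste(sprintf("%s=%g", names(loc), loc), collapse = ", "),
        "mm\n")
  }
  invisible(x)
}

#' Default configuration for the idealized LAD tree
#'
#' Documented defaults for [build_lad_tree()]: a 100 mm trunk tapering
#' linearly from 3.5 to 2.0 mm with seven primary branches ("a"--"g")
#' attached proximal to distal, every branch at least 1 mm in diameter and
#' the trunk at least 2 mm everywhere. Named stenosis locations A--D sit on
#' the trunk between successive branches; the a--b gap is wide enough to
#' hold lesions up to 16 mm long.
#'
#' @param trunk_length_mm trunk length (mm).
#' @param trunk_d_inlet_mm,trunk_d_outlet_mm trunk end diameters (mm);
#'   the taper must be monotone non-increasing.
#' @param branch_s_mm attachment arclengths of the primary branches (mm).
#' @param branch_d_mm branch diameters (mm), one per branch.
#' @param branch_length_mm branch length(s) (mm), recycled.
#' @param locations named numeric vector of trunk arclengths for the
#'   proximal-to-distal stenosis locations.
#' @return A list of class `lad_config`.
#' @export
lad_config <- function(trunk_length_mm = 100,
                       trunk_d_inlet_mm = 3.5,
                       trunk_d_outlet_mm = 2.0,
                       branch_s_mm = c(10, 30, 42, 54, 66, 78, 90),
                       branch_d_mm = c(2.0, 1.8, 1.6, 1.5, 1.3, 1.2, 1.0),
                       branch_length_mm = 20,
                       locations = c(A = 20, B = 36, C = 60, D = 84)) {
  structure(list(trunk_length_mm = trunk_length_mm,
                 trunk_d_inlet_mm = trunk_d_inlet_mm,
                 trunk_d_outlet_mm = trunk_d_outlet_mm,
                 branch_s_mm = branch_s_mm,
                 branch_d_mm = branch_d_mm,
                 branch_length_mm = rep_len(branch_length_mm,
                                            length(branch_s_mm)),
                 locations = locations),
            class = "lad_config")
}

#' Build the idealized LAD emulator tree
#'
#' Constructs a deterministic single-trunk tree with uniform-diameter primary
#' branches from an [lad_config()]. The construction enforces the anatomical
#' constraints of the emulated vessel: trunk diameter >= 2 mm over its whole
#' length, every branch >= 1 mm, and a monotone (non-increasing) trunk taper.
#'
#' @param config an [lad_config()].
#' @return A [coronary_tree()] with the trunk as inlet, one outlet per branch
#'   plus the distal trunk, and `metadata$locations` holding the named
#'   stenosis locations ordered proximal to distal.
#' @examples
#' tree <- build_lad_tree()
#' length(tree$outlets)  # 8
#' @export
build_lad_tree <- function(config = lad_config()) {
  cfg <- config
  if (cfg$trunk_d_outlet_mm > cfg$trunk_d_inlet_mm) {
    stop("trunk taper must be monotone: outlet diameter exceeds inlet diameter",
         call. = FALSE)
  }
  if (min(cfg$trunk_d_inlet_mm, cfg$trunk_d_outlet_mm) < 2) {
    stop("trunk diameter must be >= 2 mm over its full length", call. = FALSE)
  }
  nb <- length(cfg$branch_s_mm)
  if (nb > 0) {
    if (length(cfg$branch_d_mm) != nb) {
      stop("branch_d_mm must match branch_s_mm in length", call. = FALSE)
    }
    if (any(cfg$branch_d_mm < 1)) {
      stop("every branch diameter must be >= 1 mm", call. = FALSE)
    }
    if (any(diff(cfg$branch_s_mm) <= 0) ||
        any(cfg$branch_s_mm <= 0 | cfg$branch_s_mm >= cfg$trunk_length_mm)) {
      stop("branch attachments must be strictly increasing inside the trunk",
           call. = FALSE)
    }
  }
  trunk <- vessel_segment("trunk", cfg$trunk_length_mm,
                          c(cfg$trunk_d_inlet_mm, cfg$trunk_d_outlet_mm),
                          role = "trunk")
  segments <- list(trunk)
  if (nb > 0) {
    bnames <- letters[seq_len(nb)]
    for (k in seq_len(nb)) {
      segments[[k + 1L]] <- vessel_segment(
        bnames[k], cfg$branch_length_mm[k],
        c(cfg$branch_d_mm[k], cfg$branch_d_mm[k]), role = "branch")
    }
    junctions <- data.frame(parent = "trunk", s_mm = cfg$branch_s_mm,
                            child = bnames, stringsAsFactors = FALSE)
  } else {
    junctions <- NULL
  }
  loc <- cfg$locations
  if (length(loc)) {
    if (is.null(names(loc)) || any(!nzchar(names(loc)))) {
      stop("stenosis locations must be named", call. = FALSE)
    }
    if (any(diff(unname(loc)) <= 0)) {
      stop("stenosis locations must be ordered proximal to distal", call. = FALSE)
    }
    if (any(loc <= 0 | loc >= cfg$trunk_length_mm)) {
      stop("stenosis locations must lie inside the trunk", call. = FALSE)
    }
  }
  coronary_tree(segments, junctions, inlet = "trunk",
                metadata = list(locations = as.list(loc), config = unclass(cfg)))
}

#' Specify an idealized concentric stenosis
#'
#' @param ds diameter stenosis fraction in \[0, 1): the throat diameter is
#'   `(1 - ds)` times the local normal diameter.
#' @param length_mm stenotic extent length (mm, > 0).
#' @param center_s_mm arclength of the lesion centre on the trunk (mm).
#' @param shape narrowing window: `"cosine"` (smooth, with a flat throat over
#'   the central 20% for lengths > 4 mm) or `"trapezoid"` (linear ramps over
#'   40% each side, flat central 20%).
#' @return An object of class `stenosis_spec`.
#' @examples
#' stenosis_spec(0.55, 4, 20)
#' @export
stenosis_spec <- function(ds, length_mm, center_s_mm,
                          shape = c("cosine", "trapezoid")) {
  shape <- match.arg(shape)
  if (!is.numeric(ds) || ds < 0 || ds >= 1) {
    stop("ds must be a fraction in [0, 1)", call. = FALSE)
  }
  if (length_mm <= 0) stop("stenosis length must be > 0", call. = FALSE)
  structure(list(ds = ds, length_mm = length_mm, center_s_mm = center_s_mm,
                 shape = shape),
            class = "stenosis_spec")
}

#' @export
print.stenosis_spec <- function(x, ...) {
  cat(sprintf("<stenosis_spec> DS = %.0f%%, length %g mm, centre s = %g mm, %s window\n",
              100 * x$ds, x$length_mm, x$center_s_mm, x$shape))
  invisible(x)
}

# narrowing window w(t), t in [0, L]: 0 at both ends, 1 at the throat.
# cosine: full-period raised cosine for L <= 4 mm; for longer lesions the
# central 20% is clipped to w = 1 and half-cosine ramps span 40% each side.
stenosis_window <- function(spec) {
  L <- spec$length_mm
  if (spec$shape == "cosine" && L <= 4) {
    function(t) 0.5 * (1 - cos(2 * pi * pmin(pmax(t, 0), L) / L))
  } else {
    ramp <- 0.4 * L
    if (spec$shape == "cosine") {
      up <- function(t) 0.5 * (1 - cos(pi * t / ramp))
    } else {
      up <- function(t) t / ramp
    }
    function(t) {
      t <- pmin(pmax(t, 0), L)
      w <- rep(1, length(t))
      lo <- t < ramp
      hi <- t > L - ramp
      w[lo] <- up(t[lo])
      w[hi] <- up(L - t[hi])
      w
    }
  }
}

stenosis_extent <- function(spec) {
  c(spec$center_s_mm - spec$length_mm / 2, spec$center_s_mm + spec$length_mm / 2)
}

#' Insert an idealized stenosis into a tree's trunk
#'
#' Narrows the trunk diameter over the stenotic extent by
#' `d(s) = d_normal(s) * (1 - ds * w(s))` where the window `w` is 0 at the
#' extent endpoints and 1 at the throat, so the throat diameter is exactly
#' `(1 - ds)` times the local normal diameter. The input tree is not
#' modified; junction attachments and the total trunk length are preserved.
#'
#' @param tree a [coronary_tree()] (must not already carry a stenosis).
#' @param spec a [stenosis_spec()]; its extent must lie within the trunk and
#'   must not strictly contain a junction attachment point.
#' @param n_profile number of resampling points across the stenotic extent
#'   (>= 51; the d^-4 viscous quadrature downstream needs a dense throat).
#' @return A new [coronary_tree()]; `metadata$stenosis` records the spec, the
#'   extent and the local normal (pre-narrowing) throat diameter.
#' @examples
#' tree <- build_lad_tree()
#' st <- insert_stenosis(tree, stenosis_spec(0.75, 4, 20))
#' @export
insert_stenosis <- function(tree, spec, n_profile = 201) {
  stopifnot(inherits(tree, "coronary_tree"), inherits(spec, "stenosis_spec"))
  if (!is.null(tree$metadata$stenosis)) {
    stop("tree already carries a stenosis; insert into the baseline tree",
         call. = FALSE)
  }
  trunk_id <- tree$inlet
  trunk <- tree$segments[[trunk_id]]
  ext <- stenosis_extent(spec)
  if (ext[1] < -1e-9 || ext[2] > trunk$length_mm + 1e-9) {
    stop(sprintf("stenotic extent [%g, %g] mm lies outside the trunk [0, %g]",
                 ext[1], ext[2], trunk$length_mm), call. = FALSE)
  }
  jt <- tree$junctions[tree$junctions$parent == trunk_id, , drop = FALSE]
  inside <- jt$s_mm > ext[1] + 1e-9 & jt$s_mm < ext[2] - 1e-9
  if (any(inside)) {
    stop(sprintf(
      "stenotic extent [%g, %g] mm overlaps the junction to branch '%s' at s = %g mm",
      ext[1], ext[2], jt$child[which(inside)[1L]], jt$s_mm[which(inside)[1L]]),
      call. = FALSE)
  }
  d_norm_center <- segment_diameter(trunk, spec$center_s_mm)
  n_profile <- max(51L, as.integer(n_profile))
  s_new <- sort(unique(c(trunk$profile[, 1L],
                         seq(ext[1], ext[2], length.out = n_profile),
                         spec$center_s_mm)))
  d_new <- segment_diameter(trunk, s_new)
  if (spec$ds > 0) {
    w <- stenosis_window(spec)
    in_ext <- s_new >= ext[1] & s_new <= ext[2]
    d_new[in_ext] <- d_new[in_ext] * (1 - spec$ds * w(s_new[in_ext] - ext[1]))
  }
  segs <- tree$segments
  segs[[trunk_id]] <- vessel_segment(trunk_id, trunk$length_mm,
                                     cbind(s_new, d_new), role = trunk$role)
  meta <- tree$metadata
  meta$stenosis <- list(ds = spec$ds, length_mm = spec$length_mm,
                        center_s_mm = spec$center_s_mm, shape = spec$shape,
                        extent_mm = ext, normal_diameter_mm = d_norm_center,
                        throat_diameter_mm = (1 - spec$ds) * d_norm_center)
  coronary_tree(unname(segs), tree$junctions, inlet = tree$inlet,
                metadata = meta)
}
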