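#' Construct an airway tree
#'
#' An airway tree is a rooted, acyclic network of conducting-airway
#' segments, split into a `"central"` region (trachea and main bronchi)
#' and one contiguous subtree per lobe, mirroring how segmented CT airway
#' models are trimmed and partitioned for flow analysis.  Terminal
#' segments ("terminal bronchi") are the flow inlets during expiration.
#'
#' The constructor performs structural parsing only (required columns,
#' types); full invariant checking is done by [validate_tree()].
#'
#' @param segments A data frame with one row per segment and columns
#'   `id` (character), `parent_id` (character, `NA` only for the root),
#'   `region` (`"central"` or a lobe code), `length_m`, `radius_m`,
#'   `inlet_area_m2` (terminal segments only, `NA` otherwise) and
#'   `generation` (integer, 0 at the trachea).
#' @param root_id Identifier of the root segment.  If `NULL`, inferred as
#'   the unique segment with missing `parent_id`.
#' @param lobes Character vector of admissible lobe codes.
#' @return A tibble of class `"airway_tree"` with attributes `root_id` and
#'   `lobes`.
#' @seealso [validate_tree()], [split_regions()], [read_airway_tree()]
#' @export
airway_tree <- function(segments, root_id = NULL, lobes = porcine_lobes()) {
  needed <- c("id", "parent_id", "region", "length_m", "radius_m",
              "inlet_area_m2", "generation")
  missing_cols <- setdiff(needed, names(segments))
  if (length(missing_cols) > 0) {
    abort(paste0("airway tree parse error: missing field(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  seg <- as_tibble(segments)[, needed]
  seg$id <- as.character(seg$id)
  seg$parent_id <- as.character(seg$parent_id)
  seg$region <- as.character(seg$region)
  for (col in c("length_m", "radius_m", "inlet_area_m2")) {
    if (!is.numeric(seg[[col]]) && !all(is.na(seg[[col]]))) {
      abort(paste0("airway tree parse error: field '", col, "' must be numeric"))
    }
    seg[[col]] <- as.numeric(seg[[col]])
  }
  seg$generation <- as.integer(seg$generation)
  if (is.null(root_id)) {
    roots <- seg$id[is.na(seg$parent_id)]
    root_id <- if (length(roots) >= 1) roots[[1]] else NA_character_
  }
  structure(
    seg,
    root_id = as.character(root_id),
    lobes = lobes,
    class = c("airway_tree", class(tibble()))
  )
}

tree_root_id <- function(tree) attr(tree, "root_id")
tree_lobes <- function(tree) attr(tree, "lobes") %||% porcine_lobes()

#' Terminal segments of an airway tree
#'
#' A segment is terminal when no other segment names it as parent.
#'
#' @param tree An [airway_tree()].
#' @return Logical vector along the rows of `tree`.
#' @export
is_terminal <- function(tree) {
  !(tree$id %in% tree$parent_id[!is.na(tree$parent_id)])
}

#' Validate airway-tree invariants
#'
#' Checks every structural invariant of the airway-tree model: a single
#' root, unique ids, existing parents, connectedness and acyclicity,
#' positive geometry, lobar terminals with positive inlet area, at least
#' one terminal per lobe, contiguous lobar subtrees (a child of a lobar
#' segment belongs to the same lobe) and a connected central subtree
#' containing the root.
#'
#' @param tree An [airway_tree()].
#' @return Character vector of violation descriptions; empty when the tree
#'   is valid.  Each violation names the segment(s) involved.
#' @export
validate_tree <- function(tree) {
  v <- character()
  seg <- tree
  lobes <- tree_lobes(tree)

  if (anyDuplicated(seg$id)) {
    dup <- unique(seg$id[duplicated(seg$id)])
    v <- c(v, paste0("duplicate segment id(s): ", paste(dup, collapse = ", ")))
  }
  roots <- seg$id[is.na(seg$parent_id)]
  if (length(roots) == 0) {
    v <- c(v, "no root: every segment has a parent")
  } else if (length(roots) > 1) {
    v <- c(v, paste0("multiple roots (parentless segments): ",
                     paste(roots, collapse = ", ")))
  }
  rid <- tree_root_id(tree)
  if (!is.na(rid) && length(roots) == 1 && !identical(rid, roots[[1]])) {
    v <- c(v, paste0("root_id '", rid, "' is not the parentless segment '",
                     roots[[1]], "'"))
  }
  has_parent <- !is.na(seg$parent_id)
  orphan <- seg$id[has_parent & !(seg$parent_id %in% seg$id)]
  if (length(orphan) > 0) {
    v <- c(v, paste0("unknown parent for segment(s): ",
                     paste(orphan, collapse = ", ")))
  }

  bad_region <- seg$id[!(seg$region %in% c("central", lobes))]
  if (length(bad_region) > 0) {
    v <- c(v, paste0("invalid region code for segment(s): ",
                     paste(bad_region, collapse = ", ")))
  }

  bad_len <- seg$id[!is.na(seg$length_m) & seg$length_m <= 0 | is.na(seg$length_m)]
  if (length(bad_len) > 0) {
    v <- c(v, paste0("non-positive length for segment(s): ",
                     paste(bad_len, collapse = ", ")))
  }
  bad_rad <- seg$id[!is.na(seg$radius_m) & seg$radius_m <= 0 | is.na(seg$radius_m)]
  if (length(bad_rad) > 0) {
    v <- c(v, paste0("non-positive radius for segment(s): ",
                     paste(bad_rad, collapse = ", ")))
  }

  ## Reachability from the root establishes connectedness + acyclicity
  ## (n segments, n-1 parent links, all reachable => a tree).
  if (length(roots) == 1 && length(orphan) == 0 && !anyDuplicated(seg$id)) {
    children <- split(seg$id, factor(seg$parent_id, levels = seg$id))
    reached <- character()
    frontier <- roots
    while (length(frontier) > 0) {
      reached <- c(reached, frontier)
      frontier <- unlist(children[frontier], use.names = FALSE)
    }
    unreached <- setdiff(seg$id, reached)
    if (length(unreached) > 0) {
      v <- c(v, paste0("segment(s) not reachable from root (cycle or ",
                       "disconnected): ", paste(unreached, collapse = ", ")))
    }
  }

  term <- is_terminal(tree)
  central_term <- seg$id[term & seg$region == "central"]
  if (length(central_term) > 0) {
    v <- c(v, paste0("terminal segment(s) without a lobar region: ",
                     paste(central_term, collapse = ", ")))
  }
  bad_area <- seg$id[term & seg$region != "central" &
                       (is.na(seg$inlet_area_m2) | seg$inlet_area_m2 <= 0)]
  if (length(bad_area) > 0) {
    v <- c(v, paste0("terminal segment(s) without positive inlet_area_m2: ",
                     paste(bad_area, collapse = ", ")))
  }
  lobes_present <- unique(seg$region[term & seg$region %in% lobes])
  missing_lobes <- setdiff(lobes, lobes_present)
  if (length(missing_lobes) > 0) {
    v <- c(v, paste0("lobe(s) without a terminal segment: ",
                     paste(missing_lobes, collapse = ", ")))
  }

  ## Region contiguity: child of a lobar segment stays in that lobe;
  ## child of the root or of a central segment may be central or open a lobe.
  if (length(orphan) == 0) {
    parent_region <- seg$region[match(seg$parent_id, seg$id)]
    noncontig <- seg$id[!is.na(seg$parent_id) &
                          parent_region %in% lobes &
                          seg$region != parent_region]
    if (length(noncontig) > 0) {
      v <- c(v, paste0("non-contiguous region: segment(s) ",
                       paste(noncontig, collapse = ", "),
                       " differ in region from their lobar parent"))
    }
    ## central connected subtree containing the root: a central segment's
    ## parent must be central (or it is the root itself).
    central_break <- seg$id[!is.na(seg$parent_id) & seg$region == "central" &
                              !(parent_region %in% "central")]
    if (length(central_break) > 0) {
      v <- c(v, paste0("central segment(s) with non-central parent: ",
                       paste(central_break, collapse = ", ")))
    }
    if (length(roots) >= 1 && any(seg$region[seg$id %in% roots] != "central")) {
      v <- c(v, paste0("root segment ", paste(roots, collapse = ", "),
                       " must be central"))
    }
  }
  v
}

#' Partition an airway tree into central and lobar regions
#'
#' Splits the segmented airway model into a central part and the airways
#' leading to each lobe, as done when preparing a trimmed CT airway model
#' for regional flow analysis.
#'
#' @param tree A valid [airway_tree()]; validated internally.
#' @return Named list mapping `"central"` and each lobe code present to the
#'   character vector of segment ids in that region.  The sets partition
#'   the id set.
#' @export
split_regions <- function(tree) {
  v <- validate_tree(tree)
  if (length(v) > 0) {
    abort(paste0("invalid airway tree:\n- ", paste(v, collapse = "\n- ")))
  }
  regions <- c("central", intersect(tree_lobes(tree), unique(tree$region)))
  out <- lapply(regions, function(r) tree$id[tree$region == r])
  names(out) <- regions
  out
}

#' Laminar (Hagen-Poiseuille) segment resistance
#'
#' Resistance of a straight cylindrical airway segment under fully
#' developed laminar steady flow, `8 mu L / (pi r^4)`, converted from SI
#' (Pa s/m3) to the package's working units of cmH2O s/L.
#'
#' @param length_m Segment length(s) in m.
#' @param radius_m Segment radius (radii) in m.
#' @param gas A [gas_properties()] object.
#' @return Resistance(s) in cmH2O s/L; strictly positive, scaling as
#'   `r^-4`.
#' @export
#' @examples
#' segment_resistance(0.1, 0.005) # ~0.075 cmH2O s/L
segment_resistance <- function(length_m, radius_m, gas = gas_properties()) {
  if (!inherits(gas, "gas_properties")) abort("`gas` must be a gas_properties object.")
  if (any(is.na(length_m)) || any(length_m <= 0)) {
    abort("segment length must be positive.")
  }
  if (any(is.na(radius_m)) || any(radius_m <= 0)) {
    abort("segment radius must be positive.")
  }
  r_si <- 8 * gas$dynamic_viscosity * length_m / (pi * radius_m^4)
  ## Pa s/m3 -> cmH2O s/L: /98.0665 Pa per cmH2O, /1000 L per m3
  r_si / (.PA_PER_CMH2O * 1000)
}

## ---- JSON serialization -------------------------------------------------

#' Read / write airway trees as JSON
#'
#' The on-disk schema is
#' `{"root_id": str, "segments": [{"id", "parent_id", "region",
#' "length_m", "radius_m", "inlet_area_m2", "generation"}]}` with
#' `parent_id`/`inlet_area_m2` null where absent.  Numeric fields
#' round-trip at full double precision.
#'
#' @param path File path.
#' @param lobes Admissible lobe codes for schema checking.
#' @return `read_airway_tree()` returns an [airway_tree()];
#'   `write_airway_tree()` returns `path` invisibly.
#' @export
read_airway_tree <- function(path, lobes = porcine_lobes()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.list(raw) || is.null(raw$root_id)) {
    abort("airway tree schema error: missing field 'root_id'")
  }
  if (is.null(raw$segments)) {
    abort("airway tree schema error: missing field 'segments'")
  }
  seg <- as_tibble(raw$segments)
  needed <- c("id", "parent_id", "region", "length_m", "radius_m",
              "inlet_area_m2", "generation")
  for (col in needed) {
    if (!col %in% names(seg)) {
      abort(paste0("airway tree schema error: missing field 'segments.", col, "'"))
    }
  }
  bad <- setdiff(unique(seg$region), c("central", lobes))
  if (length(bad) > 0) {
    abort(paste0("airway tree schema error in field 'region': unknown code(s) ",
                 paste(bad, collapse = ", ")))
  }
  if (any(!is.na(seg$length_m) & seg$length_m <= 0)) {
    abort("airway tree schema error in field 'length_m': non-positive value")
  }
  if (any(!is.na(seg$radius_m) & seg$radius_m <= 0)) {
    abort("airway tree schema error in field 'radius_m': non-positive value")
  }
  airway_tree(seg, root_id = raw$root_id, lobes = lobes)
}

#' @param tree An [airway_tree()].
#' @rdname read_airway_tree
#' @export
write_airway_tree <- function(tree, path) {
  payload <- list(
    root_id = jsonlite::unbox(tree_root_id(tree)),
    segments = as.data.frame(tree)
  )
  ## I(17): 17 significant digits, enough to round-trip any double exactly
  json <- jsonlite::toJSON(payload, digits = I(17), na = "null", null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.airway_tree <- function(x, ...) {
  cat("<airway_tree> ", nrow(x), " segments, root '", tree_root_id(x),
      "', ", sum(is_terminal(x)), " terminals\n", sep = "")
  NextMethod()
}
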