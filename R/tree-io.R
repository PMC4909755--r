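# Tree input/output: flat parent-child CSV tables (atlas hierarchy style)
# and Newick. Volumes travel in node labels formatted as "id|volume" —
# branch lengths conventionally carry time or divergence, which the
# fragmentation model does not define, so they are left unused.

#' Read a region hierarchy table
#'
#' Expects a CSV with header columns `id`, `parent_id`, `volume` (a `name`
#' column is optional; `parent_id` empty for the root). Validates ids,
#' single-rootedness, parent references and acyclicity, and names the
#' offending row on failure. Internal nodes with more than two children are
#' accepted — real atlas hierarchies are non-binary, their multi-way branch
#' points standing for a series of binary splits at different times — but
#' the tree is flagged via `attr(tree, "binary")`, since simulator output is
#' always binary.
#'
#' @param path CSV file path.
#' @return a `parc_tree`; leaf volumes may be zero (filter with
#'   [filter_volumes()] before fitting).
#' @export
read_hierarchy_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "parent_id", "volume")
  if (!all(need %in% names(tab))) {
    stop("hierarchy CSV must have columns: ", paste(need, collapse = ", "))
  }
  id <- as.integer(tab$id)
  parent_id <- suppressWarnings(as.integer(tab$parent_id))
  parent_id[tab$parent_id %in% c("", "NA", NA)] <- NA_integer_
  volume <- as.numeric(tab$volume)
  if (anyNA(id)) stop("non-integer id at row ", which(is.na(id))[1L])
  dup <- anyDuplicated(id)
  if (dup) stop("duplicate id '", id[dup], "' at row ", dup)
  roots <- which(is.na(parent_id))
  if (length(roots) != 1L) {
    stop("expected exactly one root (blank parent_id), found ",
         length(roots),
         if (length(roots) > 1L)
           paste0(" (rows ", paste(roots, collapse = ", "), ")"))
  }
  dangling <- which(!is.na(parent_id) & !(parent_id %in% id))
  if (length(dangling)) {
    stop("row ", dangling[1L], " references missing parent '",
         parent_id[dangling[1L]], "'")
  }
  if (anyNA(volume) || any(volume < 0)) {
    bad <- which(is.na(volume) | volume < 0)[1L]
    stop("row ", bad, " has a missing or negative volume")
  }
  birth <- if ("birth_step" %in% names(tab)) {
    suppressWarnings(as.integer(tab$birth_step))
  } else {
    rep(NA_integer_, length(id))
  }
  is_parent <- id %in% parent_id[!is.na(parent_id)]
  leaf_ids <- id[!is_parent]
  tree <- new_parc_tree(id, parent_id, volume, birth, leaf_ids)
  # full validation incl. cycle detection; name the row on failure
  tryCatch(
    validate_parc_tree(tree, require_binary = FALSE,
                       allow_zero_volume = TRUE),
    error = function(e) stop("invalid hierarchy in '", path, "': ",
                             conditionMessage(e)))
  nch <- table(factor(parent_id[!is.na(parent_id)], levels = id))
  binary <- all(nch[nch > 0L] == 2L)
  if (!binary) {
    message("non-binary branch points present (",
            sum(nch > 2L), " nodes with > 2 children); ",
            "leaf statistics are unaffected")
  }
  attr(tree, "binary") <- binary
  tree
}

#' Write a region hierarchy table
#'
#' Flat CSV mirror of the tree (columns id, parent_id, name, volume,
#' birth_step, is_leaf), the same dialect [read_hierarchy_csv()] consumes.
#'
#' @param tree a `parc_tree`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hierarchy_csv <- function(tree, path) {
  stopifnot(is_parc_tree(tree))
  tab <- as.data.frame(tree)
  tab$volume <- sprintf("%.17g", tab$volume)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_label <- function(id, volume) sprintf("%d|%.17g", id, volume)

parse_label <- function(lab) {
  parts <- strsplit(lab, "|", fixed = TRUE)
  id <- vapply(parts, function(p) suppressWarnings(as.integer(p[1L])),
               integer(1))
  vol <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2L])),
                numeric(1))
  if (anyNA(id) || anyNA(vol)) {
    bad <- which(is.na(id) | is.na(vol))[1L]
    stop("malformed node label '", lab[bad], "' (expected 'id|volume')")
  }
  list(id = id, volume = vol)
}

#' Newick serialization of parcellation trees
#'
#' Writes the tree as Newick with every node labelled `id|volume`; branch
#' lengths are not used. `read_newick()` inverts the writer; topology and
#' volumes round-trip (volumes to full double precision). The degenerate
#' single-region tree is written as a bare labelled root.
#'
#' @param tree a `parc_tree` (binary).
#' @param path file path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `parc_tree` (with `birth_step` unset, as Newick does not
#'   carry it).
#' @export
write_newick <- function(tree, path) {
  stopifnot(is_parc_tree(tree))
  n_tip <- length(tree$leaf_ids)
  if (n_tip == 1L) {
    writeLines(paste0(fmt_label(tree$id[1L], tree$volume[1L]), ";"), path)
    return(invisible(path))
  }
  phy <- as_phylo_parc(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

as_phylo_parc <- function(tree) {
  validate_parc_tree(tree, require_binary = TRUE)
  tips <- tree$leaf_ids
  internals_all <- setdiff(tree$id, tips)
  rid <- root_id(tree)
  internals <- c(rid, setdiff(internals_all, rid))
  idx <- c(setNames(seq_along(tips), tips),
           setNames(length(tips) + seq_along(internals), internals))
  non_root <- tree$id[!is.na(tree$parent_id)]
  edge <- cbind(idx[as.character(tree$parent_id[match(non_root, tree$id)])],
                idx[as.character(non_root)])
  dimnames(edge) <- NULL
  phy <- structure(
    list(edge = edge, Nnode = length(internals),
         tip.label = fmt_label(tips, tree$volume[match(tips, tree$id)]),
         node.label = fmt_label(internals,
                                tree$volume[match(internals, tree$id)])),
    class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy, "cladewise")
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl("(", txt, fixed = TRUE)) {
    lab <- sub(";\\s*$", "", trimws(txt))
    lab <- gsub("^'|'$", "", lab)
    p <- parse_label(lab)
    return(new_parc_tree(p$id, NA_integer_, p$volume, NA_integer_, p$id))
  }
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("malformed Newick in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick in '", path, "'")
  n_tip <- length(phy$tip.label)
  if (is.null(phy$node.label) || length(phy$node.label) != phy$Nnode) {
    stop("Newick tree lacks internal 'id|volume' labels")
  }
  tp <- parse_label(phy$tip.label)
  np <- parse_label(phy$node.label)
  id <- c(tp$id, np$id)            # phylo index order: tips then internals
  volume <- c(tp$volume, np$volume)
  parent_id <- rep(NA_integer_, length(id))
  parent_id[phy$edge[, 2L]] <- id[phy$edge[, 1L]]
  new_parc_tree(id, parent_id, volume, rep(NA_integer_, length(id)),
                tp$id)
}
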