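# Biased fragmentation (parcellation) process.
#
# The brain starts as a single region ("parcellation unit", PU) and evolves
# by repeated binary splits: at each step a leaf region i is chosen with
# probability p_i = v_i^mu / Z and divided into two noisy halves whose
# volumes sum to the parent volume. Evolutionary time is measured by the
# number of PUs, so a run to n_target leaves takes n_target - 1 steps.

#' Split probabilities of current regions
#'
#' Probability that each current region is the next to fragment, proportional
#' to volume^mu and normalized over the whole ensemble. Computed in log space
#' with max-subtraction so extreme `mu * log(v)` cannot overflow.
#'
#' @param leaf_volumes numeric vector of positive region volumes.
#' @param mu bias exponent; `mu = 0` gives the uniform model, positive values
#'   favour splitting large regions.
#' @return numeric vector of probabilities summing to 1, aligned with
#'   `leaf_volumes`.
#' @examples
#' split_probabilities(c(2, 1), mu = 1)   # 2/3, 1/3
#' split_probabilities(c(2, 1), mu = 0)   # uniform
#' @export
split_probabilities <- function(leaf_volumes, mu) {
  if (length(leaf_volumes) == 0L) {
    stop("'leaf_volumes' must be non-empty")
  }
  if (!is.numeric(leaf_volumes) || anyNA(leaf_volumes) ||
      any(leaf_volumes <= 0)) {
    stop("all volumes must be positive")
  }
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  z <- mu * log(leaf_volumes)
  w <- exp(z - max(z))
  w / sum(w)
}

#' @rdname parc_tree
#' @export
is_parc_tree <- function(x) inherits(x, "parc_tree")

new_parc_tree <- function(id, parent_id, volume, birth_step, leaf_ids) {
  structure(
    list(id = as.integer(id), parent_id = as.integer(parent_id),
         volume = as.numeric(volume), birth_step = as.integer(birth_step),
         leaf_ids = as.integer(leaf_ids)),
    class = "parc_tree")
}

#' Parcellation trees
#'
#' A `parc_tree` records the full fragmentation history: every region ever
#' created is a node with an integer `id`, a `parent_id` (`NA` for the root),
#' a `volume`, and the simulation step at which it appeared (`birth_step`,
#' `NA` for trees read from formats that do not carry it). Leaves are the
#' current regions; `leaf_ids` keeps them in creation order.
#'
#' @param x object to test or print.
#' @param tree a `parc_tree`.
#' @name parc_tree
NULL

#' @rdname parc_tree
#' @export
root_id <- function(tree) {
  stopifnot(is_parc_tree(tree))
  tree$id[is.na(tree$parent_id)]
}

#' @rdname parc_tree
#' @export
leaf_volumes <- function(tree) {
  stopifnot(is_parc_tree(tree))
  tree$volume[match(tree$leaf_ids, tree$id)]
}

#' @rdname parc_tree
#' @export
n_leaves <- function(tree) {
  stopifnot(is_parc_tree(tree))
  length(tree$leaf_ids)
}

validate_parc_tree <- function(tree, require_binary = TRUE,
                               allow_zero_volume = FALSE) {
  stopifnot(is_parc_tree(tree))
  if (anyDuplicated(tree$id)) stop("duplicate node ids")
  nroot <- sum(is.na(tree$parent_id))
  if (nroot != 1L) stop("tree must have exactly one root, found ", nroot)
  known <- tree$parent_id[!is.na(tree$parent_id)]
  if (!all(known %in% tree$id)) stop("dangling parent_id")
  if (allow_zero_volume) {
    if (any(tree$volume < 0)) stop("volumes must be non-negative")
  } else if (any(tree$volume <= 0)) {
    stop("volumes must be positive")
  }
  nch <- table(factor(known, levels = tree$id))
  internal <- tree$id[nch > 0L]
  leaves <- tree$id[nch == 0L]
  if (!setequal(leaves, tree$leaf_ids)) stop("leaf_ids inconsistent")
  if (require_binary && any(nch[nch > 0L] != 2L)) {
    stop("internal nodes must have exactly two children")
  }
  # reachability from root guards against cycles among non-root components
  adj <- split(tree$id[!is.na(tree$parent_id)], known)
  seen <- root_id(tree)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unlist(adj[as.character(frontier)], use.names = FALSE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  if (length(seen) != length(tree$id)) stop("cycle or disconnected nodes")
  invisible(tree)
}

#' Split one leaf region into two noisy halves
#'
#' The parent of volume v is replaced by children of volume `v*r/2` and
#' `v*(2-r)/2` where `r` is drawn from Normal(1, `noise_sd`), re-drawn while
#' outside (0.02, 1.98) so volumes stay positive. The children's volumes sum
#' exactly to v. Uses R's global RNG stream.
#'
#' @param tree a `parc_tree`.
#' @param leaf_id id of a current leaf.
#' @param noise_sd standard deviation of the multiplicative split noise.
#' @param birth_step step index recorded on the children (defaults to one
#'   past the largest existing `birth_step`).
#' @return the updated `parc_tree` (one more leaf).
#' @export
split_leaf <- function(tree, leaf_id, noise_sd = 0.1, birth_step = NULL) {
  stopifnot(is_parc_tree(tree))
  if (!leaf_id %in% tree$leaf_ids) {
    stop("node ", leaf_id, " is not a current leaf")
  }
  stopifnot(noise_sd >= 0, noise_sd < 0.5)
  pos <- match(leaf_id, tree$id)
  v <- tree$volume[pos]
  r <- 1
  if (noise_sd > 0) {
    repeat {
      r <- rnorm(1L, mean = 1, sd = noise_sd)
      if (r > 0.02 && r < 1.98) break
    }
  }
  if (is.null(birth_step)) {
    birth_step <- max(tree$birth_step, 0L, na.rm = TRUE) + 1L
  }
  v1 <- v * r / 2
  v2 <- v - v1                      # exact conservation
  new_ids <- max(tree$id) + c(1L, 2L)
  tree$id <- c(tree$id, new_ids)
  tree$parent_id <- c(tree$parent_id, leaf_id, leaf_id)
  tree$volume <- c(tree$volume, v1, v2)
  tree$birth_step <- c(tree$birth_step, birth_step, birth_step)
  k <- match(leaf_id, tree$leaf_ids)
  tree$leaf_ids[k] <- new_ids[1L]   # first child replaces the parent slot
  tree$leaf_ids <- c(tree$leaf_ids, new_ids[2L])
  tree
}

#' Simulate the biased fragmentation process
#'
#' Runs the fragmentation model from a single root region until `n_target`
#' leaves exist. At every step the split probabilities are recomputed over
#' all current leaves (no caching), one leaf is selected, and [split_leaf()]
#' divides it. A single seeded RNG stream drives both the selection and the
#' split noise, in that order within each step, so runs are reproducible.
#'
#' @param mu bias exponent of the split probability (volume^mu).
#' @param n_target target number of leaf regions (>= 1).
#' @param noise_sd multiplicative split noise (default 0.10, i.e. 10 percent).
#' @param root_volume volume of the initial region (arbitrary units).
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return a `parc_tree` with `n_target` leaves whose volumes sum to
#'   `root_volume` (up to round-off).
#' @examples
#' tr <- run_fragmentation(mu = 0, n_target = 50, seed = 1)
#' sd(log(leaf_volumes(tr)))
#' @export
run_fragmentation <- function(mu, n_target, noise_sd = 0.1,
                              root_volume = 1, seed = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  stopifnot(n_target >= 1, n_target == as.integer(n_target))
  stopifnot(noise_sd >= 0, noise_sd < 0.5)
  stopifnot(root_volume > 0)
  if (!is.null(seed)) set.seed(seed)
  n_target <- as.integer(n_target)

  n_nodes <- 2L * n_target - 1L
  id <- seq_len(n_nodes) - 1L
  parent_id <- rep(NA_integer_, n_nodes)
  volume <- rep(NA_real_, n_nodes)
  birth_step <- rep(NA_integer_, n_nodes)
  volume[1L] <- root_volume
  birth_step[1L] <- 0L

  leaf_pos <- 1L                    # positions (1-based) of current leaves
  nxt <- 2L
  for (step in seq_len(n_target - 1L)) {
    k <- length(leaf_pos)
    if (k == 1L) {
      sel <- 1L
    } else {
      p <- split_probabilities(volume[leaf_pos], mu)
      sel <- sample.int(k, 1L, prob = p)
    }
    r <- 1
    if (noise_sd > 0) {
      repeat {
        r <- rnorm(1L, mean = 1, sd = noise_sd)
        if (r > 0.02 && r < 1.98) break
      }
    }
    pp <- leaf_pos[sel]
    v <- volume[pp]
    v1 <- v * r / 2
    c1 <- nxt; c2 <- nxt + 1L; nxt <- nxt + 2L
    parent_id[c(c1, c2)] <- id[pp]
    volume[c1] <- v1
    volume[c2] <- v - v1
    birth_step[c(c1, c2)] <- step
    leaf_pos[sel] <- c1
    leaf_pos <- c(leaf_pos, c2)
  }
  new_parc_tree(id, parent_id, volume, birth_step, id[leaf_pos])
}

#' Ensemble of within-run log-volume dispersions
#'
#' Runs `n_sims` independent fragmentations (compiled kernel, same process as
#' [run_fragmentation()]) and returns the within-run standard deviation of
#' `log(leaf volume)` for each run. This is the dispersion statistic
#' sigma(ln v) used throughout the mu inference.
#'
#' @inheritParams run_fragmentation
#' @param n_pu number of leaf regions per run.
#' @param n_sims number of independent runs.
#' @return numeric vector of length `n_sims`.
#' @examples
#' mean(simulate_sigma_ensemble(100, mu = 0, n_sims = 50, seed = 1))
#' @export
simulate_sigma_ensemble <- function(n_pu, mu = 0, noise_sd = 0.1,
                                    n_sims = 100L, root_volume = 1,
                                    seed = NULL) {
  stopifnot(n_pu >= 1, n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  cpp_sigma_ensemble(as.integer(n_pu), mu, noise_sd, as.integer(n_sims),
                     root_volume)
}

#' @rdname parc_tree
#' @param ... unused.
#' @export
print.parc_tree <- function(x, ...) {
  lv <- leaf_volumes(x)
  cat("Parcellation tree:", length(x$id), "nodes,", length(x$leaf_ids),
      "leaves\n")
  cat(sprintf("  root volume %.6g, leaf volume sum %.6g\n",
              x$volume[is.na(x$parent_id)], sum(lv)))
  if (length(lv) > 1L && all(lv > 0)) {
    cat(sprintf("  sigma(ln v) = %.4f\n", sd(log(lv))))
  }
  invisible(x)
}

#' @rdname parc_tree
#' @param object a `parc_tree`.
#' @export
summary.parc_tree <- function(object, ...) {
  lv <- leaf_volumes(object)
  out <- list(n_nodes = length(object$id), n_leaves = length(lv),
              root_volume = object$volume[is.na(object$parent_id)],
              leaf_volume_sum = sum(lv),
              sigma_log = if (all(lv > 0)) sd(log(lv)) else NA_real_)
  class(out) <- "summary.parc_tree"
  out
}

#' @export
print.summary.parc_tree <- function(x, ...) {
  cat("Parcellation tree summary\n")
  cat("  nodes:      ", x$n_nodes, "\n")
  cat("  leaves:     ", x$n_leaves, "\n")
  cat("  root volume:", format(x$root_volume), "\n")
  cat("  sigma(ln v):", format(x$sigma_log, digits = 4), "\n")
  invisible(x)
}

#' @rdname parc_tree
#' @export
as.data.frame.parc_tree <- function(x, ...) {
  data.frame(id = x$id, parent_id = x$parent_id,
             name = paste0("region_", x$id), volume = x$volume,
             birth_step = x$birth_step,
             is_leaf = x$id %in% x$leaf_ids)
}

#' Leaf depths of a parcellation tree
#'
#' Number of splits separating each leaf from the root; with no split noise
#' a leaf at depth d has volume `root_volume / 2^d`.
#'
#' @param tree a `parc_tree`.
#' @return integer vector aligned with `tree$leaf_ids`.
#' @export
leaf_depths <- function(tree) {
  stopifnot(is_parc_tree(tree))
  parent_pos <- match(tree$parent_id, tree$id)  # NA at root
  vapply(match(tree$leaf_ids, tree$id), function(pos) {
    d <- 0L
    while (!is.na(parent_pos[pos])) {
      pos <- parent_pos[pos]
      d <- d + 1L
    }
    d
  }, integer(1))
}
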