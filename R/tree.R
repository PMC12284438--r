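#' Vascular tree of vessel segments
#'
#' A rooted binary tree of cylindrical vessel segments. Each segment has a
#' single (untapered) reference radius and a wall thickness expressed as a
#' ratio of the radius. Junctions have exactly two children; segments with
#' no children are terminal outlets.
#'
#' @param segments A data.frame with columns `id` (character or integer,
#'   unique), `parent_id` (NA or "" for the root), `length_cm`,
#'   `radius_cm`, and optionally `wall_ratio` (h0/r0, default 0.10) and
#'   `n_grid` (spatial points for the flow solver, default chosen by the
#'   solver).
#' @param default_wall_ratio Wall thickness ratio used where `wall_ratio`
#'   is absent.
#' @return Object of class `vascular_tree`: list with `segments`
#'   (normalized data.frame), `root` (id), `terminals` (ids), and
#'   `children` (named list of child ids).
#' @export
vascular_tree <- function(segments, default_wall_ratio = 0.10) {
  req <- c("id", "parent_id", "length_cm", "radius_cm")
  if (!all(req %in% names(segments)))
    stop("segments must have columns: ", paste(req, collapse = ", "))
  seg <- as.data.frame(segments, stringsAsFactors = FALSE)
  seg$id <- as.character(seg$id)
  seg$parent_id <- as.character(seg$parent_id)
  seg$parent_id[is.na(seg$parent_id) | seg$parent_id == ""] <- NA_character_
  if (anyDuplicated(seg$id)) stop("duplicate segment ids")
  if (!all(seg$length_cm > 0)) stop("segment lengths must be positive")
  if (!all(seg$radius_cm > 0)) stop("segment radii must be positive")
  if (is.null(seg$wall_ratio)) seg$wall_ratio <- default_wall_ratio
  seg$wall_ratio[is.na(seg$wall_ratio)] <- default_wall_ratio
  if (!all(seg$wall_ratio > 0 & seg$wall_ratio < 1))
    stop("wall_ratio must lie in (0, 1)")

  root <- seg$id[is.na(seg$parent_id)]
  if (length(root) != 1L)
    stop("tree must have exactly one root; found ", length(root))
  if (!all(seg$parent_id[!is.na(seg$parent_id)] %in% seg$id))
    stop("parent_id refers to unknown segment")
  children <- split(seg$id[!is.na(seg$parent_id)],
                    factor(seg$parent_id[!is.na(seg$parent_id)],
                           levels = seg$id))
  n_child <- lengths(children)
  if (!all(n_child %in% c(0L, 2L)))
    stop("every junction must have exactly 2 children; offending: ",
         paste(seg$id[n_child == 1L | n_child > 2L], collapse = ", "))
  # connectivity / acyclicity: walk from root
  seen <- character(0); stack <- root
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (cur %in% seen) stop("cycle detected at segment ", cur)
    seen <- c(seen, cur)
    stack <- c(stack, children[[cur]])
  }
  if (length(seen) != nrow(seg))
    stop("tree is not connected: ",
         paste(setdiff(seg$id, seen), collapse = ", "), " unreachable")
  seg$generation <- NA_integer_
  seg$generation[seg$id == root] <- 0L
  ord <- seen  # root-first order
  for (id in ord[-1]) {
    p <- seg$parent_id[seg$id == id]
    seg$generation[seg$id == id] <- seg$generation[seg$id == p] + 1L
  }
  structure(list(segments = seg, root = root,
                 terminals = seg$id[n_child[seg$id] == 0L],
                 children = children),
            class = "vascular_tree")
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf(
    "Vascular tree: %d segments, %d terminals, %d generations, root radius %.3g cm\n",
    nrow(x$segments), length(x$terminals), max(x$segments$generation),
    x$segments$radius_cm[x$segments$id == x$root]))
  invisible(x)
}

#' Read / write a vascular tree as CSV
#'
#' CSV columns: `id,parent_id,length_cm,radius_cm[,wall_ratio]`; the root
#' row has an empty `parent_id`.
#'
#' @param path File path.
#' @param ... Passed to [vascular_tree()].
#' @return A `vascular_tree`.
#' @export
read_tree_csv <- function(path, ...) {
  vascular_tree(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c(id = "character",
                                               parent_id = "character")),
                ...)
}

#' @rdname read_tree_csv
#' @param tree A `vascular_tree`.
#' @export
write_tree_csv <- function(tree, path) {
  seg <- tree$segments
  seg$parent_id[is.na(seg$parent_id)] <- ""
  utils::write.csv(
    seg[, c("id", "parent_id", "length_cm", "radius_cm", "wall_ratio")],
    path, row.names = FALSE)
  invisible(path)
}
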