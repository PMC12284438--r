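#' Read / write constitutive parameters as JSON
#'
#' JSON keys: `c_kPa`, `k1_kPa`, `k2`, `beta_deg`.
#'
#' @param path File path.
#' @return An [ho_params()].
#' @export
read_ho_params_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  ho_params(d$c_kPa, d$k1_kPa, d$k2, d$beta_deg)
}

#' @rdname read_ho_params_json
#' @param params An [ho_params()].
#' @export
write_ho_params_json <- function(params, path) {
  jsonlite::write_json(
    list(c_kPa = params$c_kpa, k1_kPa = params$k1_kpa, k2 = params$k2,
         beta_deg = params$beta_deg),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a vascular tree as nested JSON
#'
#' Each node carries `id`, `length_cm`, `radius_cm`, optional
#' `wall_ratio`, and a `children` array.
#'
#' @param path File path.
#' @param ... Passed to [vascular_tree()].
#' @return A [vascular_tree()].
#' @export
read_tree_json <- function(path, ...) {
  nd <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- list()
  walk <- function(node, parent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.character(node$id), parent_id = parent,
      length_cm = node$length_cm, radius_cm = node$radius_cm,
      wall_ratio = if (is.null(node$wall_ratio)) NA_real_
                   else node$wall_ratio,
      stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, as.character(node$id))
  }
  walk(nd, NA_character_)
  vascular_tree(do.call(rbind, rows), ...)
}

#' @rdname read_tree_json
#' @param tree A [vascular_tree()].
#' @export
write_tree_json <- function(tree, path) {
  seg <- tree$segments
  build <- function(id) {
    i <- which(seg$id == id)
    ch <- tree$children[[id]]
    list(id = id, length_cm = seg$length_cm[i],
         radius_cm = seg$radius_cm[i], wall_ratio = seg$wall_ratio[i],
         children = lapply(ch, build))
  }
  jsonlite::write_json(build(tree$root), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
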