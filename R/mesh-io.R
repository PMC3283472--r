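#' Write / read a mesh description as JSON
#'
#' Plain-text interchange format for the hybrid mesh: node coordinates,
#' hexahedral connectivity with region/structure labels, beam and spring
#' tables, and the named node groups. Round-trips losslessly through
#' [read_mesh_json()].
#'
#' @param mesh a [spine_mesh()].
#' @param path output file path (conventionally .json).
#' @rdname mesh-json
#' @return the path (write) or a `spine_mesh` (read), invisibly for write.
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(
    nodes = unname(apply(mesh$nodes, 1, as.numeric, simplify = FALSE)),
    hex_conn = if (is.null(mesh$hex_conn)) NULL else
      unname(apply(mesh$hex_conn, 1, as.integer, simplify = FALSE)),
    hex_region = mesh$hex_region,
    hex_structure = mesh$hex_structure,
    beams = mesh$beams,
    springs = mesh$springs,
    node_groups = lapply(mesh$node_groups, function(g) {
      list(ids = as.integer(unname(g)),
           names = if (is.null(names(g))) NULL else names(g))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname mesh-json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(obj$node_groups, function(g) {
    ids <- as.integer(g$ids)
    if (!is.null(g$names)) names(ids) <- g$names
    ids
  })
  as_df <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!nrow(df)) NULL else df
  }
  as_mat <- function(x, nc, int = FALSE) {
    if (is.null(x)) return(NULL)
    if (!is.matrix(x)) x <- matrix(unlist(x), ncol = nc, byrow = TRUE)
    if (int) storage.mode(x) <- "integer"
    x
  }
  spine_mesh(as_mat(obj$nodes, 3),
             hex_conn = as_mat(obj$hex_conn, 8, int = TRUE),
             hex_region = obj$hex_region,
             hex_structure = obj$hex_structure,
             beams = as_df(obj$beams), springs = as_df(obj$springs),
             node_groups = groups)
}
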