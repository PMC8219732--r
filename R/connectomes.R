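#' Optional real-connectome integration data
#'
#' The published motif counts for the public connectomes (for example 6894
#' undirected triangles and 123,264 undirected rectangles in the MICrONS
#' v185 soma subgraph, and seven antennal-lobe-to-Kenyon-cell motif
#' instances in Hemibrain v1.2) require downloading those datasets, which is
#' deliberately outside the test loop. If a local copy is available, point
#' the `MOTIFQUERY_CONNECTOME_DIR` environment variable at a directory
#' containing `<name>.csv` edgelist files (see
#' `system.file("extdata", "connectomes", "README.md", package =
#' "motifquery")` for fetch instructions) and the skipped-by-default
#' integration tests will run against them.
#'
#' @param name dataset name: "celegans", "microns", or "hemibrain".
#' @return `connectome_available()` returns TRUE when the named dataset is
#'   present locally; `read_connectome()` returns the host graph or errors
#'   with fetch instructions.
#' @export
connectome_available <- function(name = c("celegans", "microns", "hemibrain")) {
  name <- match.arg(name)
  dir <- Sys.getenv("MOTIFQUERY_CONNECTOME_DIR", "")
  nzchar(dir) && file.exists(file.path(dir, paste0(name, ".csv")))
}

#' @rdname connectome_available
#' @export
read_connectome <- function(name = c("celegans", "microns", "hemibrain")) {
  name <- match.arg(name)
  if (!connectome_available(name)) {
    stop("connectome dataset '", name, "' is not available locally. ",
         "Download it and set MOTIFQUERY_CONNECTOME_DIR; see the fetch ",
         "instructions in ",
         system.file("extdata", "connectomes", "README.md",
                     package = "motifquery"))
  }
  dir <- Sys.getenv("MOTIFQUERY_CONNECTOME_DIR")
  path <- file.path(dir, paste0(name, ".csv"))
  sidecar <- file.path(dir, paste0(name, "_nodes.csv"))
  read_host(path, format = "edgelist", directed = TRUE,
            node_attrs = if (file.exists(sidecar)) sidecar)
}
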