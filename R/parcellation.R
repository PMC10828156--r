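#' Parcellation schemes
#'
#' A parcellation assigns each cortical node to exactly one resting-state
#' network. The default configuration mirrors a 400-node cortical
#' parcellation with seven canonical resting-state networks (visual,
#' sensorimotor, limbic, frontoparietal, default mode, dorsal and ventral
#' attention).
#'
#' @param n_nodes number of cortical nodes (parcels).
#' @param n_networks number of networks the nodes are assigned to.
#' @param seed integer seed; fixes the (shuffled) node-to-network map.
#' @param network_names optional character vector of length `n_networks`.
#' @param centroids optional `n_nodes x 3` matrix of node centroids in mm.
#'
#' @return An object of class `parcellation`: a list with `n_nodes`,
#'   `n_networks`, `network_of` (integer vector, 1-based network index per
#'   node), `network_names` and optional `centroids`.
#' @export
generate_parcellation <- function(n_nodes, n_networks = 7L, seed = 1L,
                                  network_names = NULL, centroids = NULL) {
  n_nodes <- as.integer(n_nodes)
  n_networks <- as.integer(n_networks)
  if (n_nodes < 1L || n_networks < 1L)
    stop("n_nodes and n_networks must be positive")
  if (n_networks > n_nodes)
    stop("n_networks must not exceed n_nodes")
  if (is.null(network_names))
    network_names <- default_network_names(n_networks)
  if (length(network_names) != n_networks)
    stop("network_names must have length n_networks")
  # near-balanced partition: sizes differ by at most one
  base <- n_nodes %/% n_networks
  extra <- n_nodes %% n_networks
  sizes <- rep(base, n_networks) + c(rep(1L, extra), rep(0L, n_networks - extra))
  assign <- rep(seq_len(n_networks), times = sizes)
  with_seed(seed, {
    assign <- sample(assign)
  })
  structure(
    list(n_nodes = n_nodes, n_networks = n_networks,
         network_of = assign, network_names = network_names,
         centroids = centroids),
    class = "parcellation")
}

default_network_names <- function(n) {
  canonical <- c("visual", "sensorimotor", "dorsal_attention",
                 "ventral_attention", "limbic", "frontoparietal",
                 "default_mode")
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, paste0("network_", seq.int(length(canonical) + 1L, n)))
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d nodes, %d networks (%s)\n",
              x$n_nodes, x$n_networks,
              paste(x$network_names, collapse = ", ")))
  invisible(x)
}

validate_parcellation <- function(parcellation) {
  stopifnot(inherits(parcellation, "parcellation"))
  if (length(parcellation$network_of) != parcellation$n_nodes)
    stop("parcellation: network assignment length mismatch")
  if (!all(parcellation$network_of %in% seq_len(parcellation$n_networks)))
    stop("parcellation: network index out of range")
  invisible(parcellation)
}

#' Read / write a parcellation as a two-column text file
#'
#' The on-disk format is a tab-separated table with columns `node`
#' (0-based index) and `network` (1-based network index); network names are
#' stored in a header comment line.
#'
#' @param parcellation a `parcellation` object.
#' @param path file path.
#' @return `write_parcellation` returns `path` invisibly;
#'   `read_parcellation` returns a `parcellation`.
#' @export
write_parcellation <- function(parcellation, path) {
  validate_parcellation(parcellation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# networks: ",
                    paste(parcellation$network_names, collapse = ",")), con)
  writeLines("node\tnetwork", con)
  writeLines(sprintf("%d\t%d", seq_len(parcellation$n_nodes) - 1L,
                     parcellation$network_of), con)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  header <- readLines(path, n = 1L)
  names <- NULL
  if (startsWith(header, "# networks:"))
    names <- strsplit(trimws(sub("# networks:", "", header)), ",")[[1]]
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  node <- as.integer(tab$node)
  if (!identical(sort(node), seq_along(node) - 1L))
    stop("parcellation file: node indices must form a contiguous 0-based range")
  net <- as.integer(tab$network)[order(node)]
  n_networks <- max(net)
  if (is.null(names)) names <- default_network_names(n_networks)
  structure(
    list(n_nodes = length(net), n_networks = n_networks,
         network_of = net, network_names = names, centroids = NULL),
    class = "parcellation")
}
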