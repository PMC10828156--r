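#' Nodal network connectivity metrics
#'
#' For node i in network g, within-network connectivity is the sum of its
#' weights to nodes of g divided by E_g, the number of edges in the
#' network; inter-network connectivity is the sum of its weights to nodes
#' outside g with the same denominator; the ratio score divides the two.
#'
#' By default E_g counts the *nonzero* within-network edges (unordered
#' pairs) of network g in the subject's own thresholded matrix — the
#' normalized-strength convention on subject-specific graphs. Set
#' `denominator = "all_pairs"` to use the number of possible pairs, and
#' `double_count = TRUE` to count edges as summed degrees (factor 2).
#' Networks with E_g = 0 yield metric value 0 for their nodes.
#'
#' @param connectome a `connectome` (or plain symmetric matrix).
#' @param parcellation the matching `parcellation`.
#' @param denominator `"subject_edges"` (default) or `"all_pairs"`.
#' @param double_count count each edge twice in the denominator.
#' @return numeric vector of length `n_nodes` with attribute `"metric"`.
#' @export
within_network_connectivity <- function(connectome, parcellation,
                                        denominator = c("subject_edges", "all_pairs"),
                                        double_count = FALSE) {
  nm <- nodal_numerators(connectome, parcellation, denominator, double_count)
  structure(nm$within_num / nm$denom, metric = "within",
            names = paste0("node", seq_along(nm$within_num)))
}

#' @rdname within_network_connectivity
#' @export
inter_network_connectivity <- function(connectome, parcellation,
                                       denominator = c("subject_edges", "all_pairs"),
                                       double_count = FALSE) {
  nm <- nodal_numerators(connectome, parcellation, denominator, double_count)
  structure(nm$inter_num / nm$denom, metric = "inter",
            names = paste0("node", seq_along(nm$inter_num)))
}

#' Ratio of within- to inter-network connectivity
#'
#' Elementwise `within / inter`; nodes with zero inter-network connectivity
#' get ratio 0 (kept finite; flagged via attribute `"zero_inter"`).
#'
#' @param within,inter equal-length numeric vectors.
#' @return numeric vector with attribute `"metric" = "ratio"`.
#' @export
ratio_score <- function(within, inter) {
  if (length(within) != length(inter))
    stop("within and inter must have equal length")
  zero <- inter == 0
  r <- ifelse(zero, 0, within / inter)
  structure(as.numeric(r), metric = "ratio", zero_inter = which(zero),
            names = names(within))
}

# Shared numerators/denominators for the nodal metrics. The per-network
# denominator is replicated to the network's nodes; E_g = 0 maps to Inf so
# the division yields 0 without a branch.
nodal_numerators <- function(connectome, parcellation,
                             denominator = c("subject_edges", "all_pairs"),
                             double_count = FALSE) {
  denominator <- match.arg(denominator)
  m <- as_connectome_matrix(connectome)
  validate_parcellation(parcellation)
  if (nrow(m) != parcellation$n_nodes)
    stop("connectome / parcellation dimension mismatch")
  net <- parcellation$network_of
  n <- nrow(m)
  strength <- rowSums(m)
  within_num <- numeric(n)
  denom <- numeric(n)
  for (g in seq_len(parcellation$n_networks)) {
    ing <- net == g
    sub <- m[ing, ing, drop = FALSE]
    within_num[ing] <- rowSums(sub)
    eg <- if (denominator == "subject_edges")
      sum(sub[upper.tri(sub)] != 0)
    else choose(sum(ing), 2)
    if (double_count) eg <- 2 * eg
    denom[ing] <- if (eg == 0) Inf else eg
  }
  list(within_num = within_num, inter_num = strength - within_num,
       denom = denom)
}

#' All three nodal metrics of one connectome
#'
#' @inheritParams within_network_connectivity
#' @return list with numeric vectors `within`, `inter`, `ratio`.
#' @export
nodal_metrics <- function(connectome, parcellation,
                          denominator = c("subject_edges", "all_pairs"),
                          double_count = FALSE) {
  nm <- nodal_numerators(connectome, parcellation, denominator, double_count)
  w <- structure(nm$within_num / nm$denom, metric = "within")
  b <- structure(nm$inter_num / nm$denom, metric = "inter")
  list(within = w, inter = b, ratio = ratio_score(w, b))
}
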