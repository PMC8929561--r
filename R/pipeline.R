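#' Build a residue-grain structure network from a structure ensemble
#'
#' Convenience pipeline: extract carbon-contact (and optionally
#' hydrogen-bond) timelines from the ensemble, assemble the atom-grain
#' network, optionally restrict to inter-sidechain interactions, and
#' aggregate to one node per residue.
#'
#' @param ensemble a `structure_ensemble` (e.g. from [read_pdb_ensemble()]).
#' @param contact_cutoff carbon-contact distance cutoff, Angstrom
#'   (default 5).
#' @param hbonds also extract hydrogen bonds (default `FALSE`; contact-only
#'   networks are the common setting for single-structure centrality
#'   analysis).
#' @param sidechain_only keep only interactions whose atoms are all
#'   sidechain atoms.
#' @param min_occupancy drop edges present in fewer than this fraction of
#'   frames (default 0).
#' @return a residue-grain `psn`.
#' @export
network_from_ensemble <- function(ensemble, contact_cutoff = 5,
                                  hbonds = FALSE, sidechain_only = FALSE,
                                  min_occupancy = 0) {
  records <- extract_contacts(ensemble, cutoff = contact_cutoff)
  if (hbonds) {
    hb <- extract_hbonds(ensemble)
    hb$approximate <- NULL
    records <- rbind(records, hb)
  }
  if (nrow(records) == 0L) stop("no interactions found in ensemble")
  net <- build_network(records, ensemble$frames)
  net <- filter_network(net, min_occupancy = min_occupancy,
                        sidechain_only = sidechain_only)
  aggregate_to_groups(net)
}

#' Score network nodes with one of the allosteric prediction methods
#'
#' Dispatches to the node correlation factor (`"NCF"`), its difference
#' variant against a reference network (`"DNCF"`), betweenness centrality
#' (`"BC"`) or characteristic path length centrality (`"CPLC"`).
#' Correlation-factor scores are reported in raw bits; centrality scores are
#' min-max normalised, the convention used for ranking residues.
#'
#' @param network a `psn`.
#' @param method one of `"NCF"`, `"DNCF"`, `"BC"`, `"CPLC"`.
#' @param reference reference `psn`, required for `"DNCF"`.
#' @return named numeric score vector with a `method` attribute.
#' @export
score_nodes <- function(network, method = c("NCF", "DNCF", "BC", "CPLC"),
                        reference = NULL) {
  method <- match.arg(method)
  switch(method,
    NCF = ncf(network),
    DNCF = dncf(network, reference),
    BC = betweenness_centrality(network),
    CPLC = cplc(network))
}
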