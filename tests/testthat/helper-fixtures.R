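# Small hand-built networks used across tests.

aid <- function(res, atom = "CB", chain = "A", resname = "ALA") {
  sprintf("%s:%d:%s:%s", chain, res, resname, atom)
}

rid <- function(res, chain = "A", resname = "ALA") {
  sprintf("%s:%d:%s", chain, res, resname)
}

## triangle with two identical-timeline edges and one independent edge
triangle_network <- function() {
  rec <- timeline_records(
    source = c(aid(1), aid(2), aid(1)),
    target = c(aid(2), aid(3), aid(3)),
    type = "contact",
    timeline = list(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 1, 0, 1)))
  build_network(rec, 4)
}

## two residues; R1 holds atoms a1 (CB) and a2 (CG), R2 holds b1 (CB)
two_residue_records <- function() {
  timeline_records(
    source = c("A:1:LEU:CB", "A:1:LEU:CG"),
    target = c("A:2:PHE:CB", "A:2:PHE:CB"),
    type = "contact",
    timeline = list(c(1, 0), c(1, 1)))
}

## path to the optional PDZ2 benchmark fixtures (not redistributable; see
## the acceptance tests)
pdz2_path <- function(file) {
  system.file("extdata", "pdz2", file, package = "psnet")
}
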