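## Small hand-built networks shared across test files. All built in
## code; vertex names chosen so tests can refer to them.

## two vertex-disjoint single-reticulation cycles chained by a cut edge
chained_cycles <- function() {
  phynet(rbind(
    c("rho", "e1"), c("e1", "x4"), c("e1", "e2"),
    c("e2", "x5"), c("e2", "e3"), c("e3", "x6"), c("e3", "s1"),
    c("s1", "a1"), c("a1", "x7"), c("a1", "r1"),
    c("s1", "b1"), c("b1", "x8"), c("b1", "r1"),
    c("r1", "s2"),
    c("s2", "p1"), c("p1", "x1"), c("p1", "r2"),
    c("s2", "q1"), c("q1", "x2"), c("q1", "r2"),
    c("r2", "x3")),
    stats::setNames(paste0("x", 1:8), paste0("x", 1:8)))
}

## two blobs, the children of the upper one being the lower source plus
## two leaves, and the lower blob having six leaf children; with the
## character below, exactly one blob is informative
two_blob_net <- function() {
  phynet(rbind(
    c("rho", "s1"),
    c("s1", "a1"), c("a1", "x7"), c("a1", "r1"),
    c("s1", "b1"), c("b1", "x8"), c("b1", "r1"),
    c("r1", "s2"),
    c("s2", "p1"), c("p1", "x1"), c("p1", "p2"),
    c("p2", "x2"), c("p2", "p3"), c("p3", "x3"), c("p3", "r2"),
    c("s2", "q1"), c("q1", "x4"), c("q1", "q2"),
    c("q2", "x5"), c("q2", "r2"),
    c("r2", "x6")),
    stats::setNames(paste0("x", 1:8), paste0("x", 1:8)))
}

two_blob_char <- function() {
  as_phychar(stats::setNames(c("1", rep("0", 7L)), paste0("x", 1:8)))
}

## one reticulation feeding a cherry: has a parental tree that is not
## displayed
retic_cherry_net <- function() {
  phynet(rbind(
    c("rho", "t0"),
    c("t0", "t1"), c("t1", "x1"), c("t1", "r"),
    c("t0", "t2"), c("t2", "r"), c("t2", "x4"),
    c("r", "c"), c("c", "x2"), c("c", "x3")),
    stats::setNames(paste0("x", 1:4), paste0("x", 1:4)))
}

## the 5-cycle unrooted network with pendant leaves a..e in circular
## order
five_cycle_unet <- function() {
  cyc <- c("va", "vb", "vc", "vd", "ve")
  unet(rbind(cbind(cyc, c(cyc[-1L], cyc[1L])),
             cbind(cyc, c("a", "b", "c", "d", "e"))),
       stats::setNames(c("a", "b", "c", "d", "e"), c("a", "b", "c", "d", "e")))
}

five_cycle_char <- function() {
  as_phychar(c(a = "0", b = "0", c = "0", d = "1", e = "1"))
}
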