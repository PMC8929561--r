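test_that("mutual information reproduces frozen worked examples", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  # direct summation over the 4-frame joint histogram:
  # p(0,0)=1/2, p(0,1)=1/4, p(1,1)=1/4 -> 3/2 - 2*H(1/4,3/4)/... = 0.3112781
  expect_equal(mutual_information(c(0, 0, 0, 1), c(0, 0, 1, 1)),
               mi_oracle(c(0, 0, 0, 1), c(0, 0, 1, 1)))
  expect_equal(mutual_information(c(0, 0, 0, 1), c(0, 0, 1, 1)),
               0.311278124459133, tolerance = 1e-12)
  expect_error(mutual_information(c(0, 1), c(0, 1, 1)), "length mismatch")
})

test_that("mutual information identities hold on randomised timelines", {
  for (seed in 1:25) {
    xy <- withr::with_seed(seed, list(x = sample(0:3, 60, replace = TRUE),
                                      y = sample(0:2, 60, replace = TRUE)))
    x <- xy$x; y <- xy$y
    i_xy <- mutual_information(x, y)
    expect_equal(i_xy, mutual_information(y, x))          # symmetry
    expect_equal(mutual_information(x, x), timeline_entropy(x))
    expect_gte(i_xy, 0)
    expect_lte(i_xy, min(timeline_entropy(x), timeline_entropy(y)) + 1e-12)
    expect_equal(i_xy, mi_oracle(x, y))
  }
})

test_that("joint frame permutation preserves MI; marginal permutation erodes it", {
  gen <- generate_coupled_timelines(1, frames = 400, coupling = 0.9, seed = 11)
  x <- gen[[1]]$x; y <- gen[[1]]$y
  i0 <- mutual_information(x, y)
  perm <- withr::with_seed(42, sample(length(x)))
  expect_equal(mutual_information(x[perm], y[perm]), i0)
  # permuting one side alone destroys the coupling down to the bias floor
  bias_floor <- 1 / (2 * length(x) * log(2)) # (|X|-1)(|Y|-1)/(2T ln2), binary
  shuffled <- vapply(1:20, function(s) {
    p <- withr::with_seed(s, sample(length(x)))
    mutual_information(x, y[p])
  }, 0)
  expect_lt(mean(shuffled), i0 / 10)
  expect_lt(mean(shuffled), 10 * bias_floor)
})

test_that("difference MI matches the union-alphabet summation and sign-flips", {
  x <- c(0, 1, 0, 1)
  expect_equal(difference_mutual_information(x, x, x, x), 0.0)
  # target pair identical binary; reference pair independent
  xr <- c(0, 0, 1, 1); yr <- c(0, 1, 0, 1)
  expect_equal(difference_mutual_information(x, x, xr, yr), 1.0)
  expect_equal(difference_mutual_information(xr, yr, x, x), -1.0)
  # reference absent-by-convention reduces to plain MI
  expect_equal(difference_mutual_information(x, x), 1.0)

  for (seed in 1:10) {
    tl <- withr::with_seed(seed, list(
      x = sample(0:2, 40, replace = TRUE), y = sample(0:2, 40, replace = TRUE),
      xr = sample(0:3, 25, replace = TRUE), yr = sample(0:1, 25, replace = TRUE)))
    expect_equal(
      difference_mutual_information(tl$x, tl$y, tl$xr, tl$yr),
      dmi_oracle(tl$x, tl$y, tl$xr, tl$yr))
  }
})

test_that("ECF sums neighbour MI with the correct neighbourhood semantics", {
  net <- triangle_network()
  # ECF(e1) = I(X;Y) + I(X;Z) = 1 + 0
  expect_equal(ecf(net, aid(1), aid(2), "contact"), 1.0)

  single <- build_network(
    timeline_records(aid(1), aid(2), "contact", list(c(0, 1, 0, 1))), 4)
  expect_equal(ecf(single, aid(1), aid(2), "contact"), 0)  # no neighbours

  # parallel edges: counted exactly once, self-information excluded
  par <- build_network(timeline_records(
    source = c(aid(1), aid(1)), target = c(aid(2), aid(2)),
    type = c("contact", "hbond"),
    timeline = list(c(0, 1, 0, 1), c(0, 1, 0, 1))), 4)
  expect_equal(ecf(par, aid(1), aid(2), "contact"), 1.0)

  expect_error(ecf(net, aid(1), aid(9), "contact"), "edge not found")
})

test_that("NCF sums adjacent-edge ECF scores per node", {
  net <- triangle_network()
  s <- ncf(net)
  expect_equal(unname(s[aid(2)]), 2.0)
  expect_equal(unname(s[aid(1)]), 1.0)
  expect_equal(attr(s, "method"), "NCF")

  # all-constant timelines carry no information
  const <- build_network(timeline_records(
    source = c(aid(1), aid(2)), target = c(aid(2), aid(3)),
    type = "contact", timeline = list(c(1, 1, 1), c(1, 1, 1))), 3)
  expect_true(all(ncf(const) == 0))
})

test_that("ECF/NCF/DNCF match the literal indicator-function enumerator", {
  for (seed in 1:40) {
    net <- random_network(seed)
    # NCF route
    expect_equal(unclass(ncf(net)), ncf_oracle(net),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # DNCF route against an independently drawn reference network
    ref <- random_network(seed + 1000)
    lookup <- ref_lookup_oracle(net, ref)
    expect_equal(unclass(dncf(net, ref)), ncf_oracle(net, lookup),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("edge matching follows match-location semantics", {
  net <- triangle_network()
  m <- match_edges(net, net)
  expect_true(all(!vapply(m, is.null, TRUE)))   # identical topologies: bijection
  expect_equal(nrow(attr(m, "reference_only")), 0L)

  # reference with an extra edge: reported but not mapped
  extra <- build_network(timeline_records(
      source = c(aid(1), aid(2), aid(1), aid(3)),
      target = c(aid(2), aid(3), aid(3), aid(4)),
      type = "contact",
      timeline = list(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 1, 0, 1),
                      c(1, 0, 1, 0))), 4)
  m2 <- match_edges(net, extra)
  expect_equal(nrow(attr(m2, "reference_only")), 1L)
  expect_true(all(!vapply(m2, is.null, TRUE)))

  # target-only edge maps to an absent reference: contribution is plain MI
  m3 <- match_edges(extra, net)
  expect_equal(sum(vapply(m3, is.null, TRUE)), 1L)

  grp <- aggregate_to_groups(net)
  expect_error(match_edges(net, grp), "grain mismatch")
})

test_that("DNCF cancels on identical networks and sign-flips under swap", {
  for (seed in c(3, 9, 21)) {
    net <- random_network(seed)
    expect_true(all(abs(dncf(net, net)) < 1e-12))
    # same topology, different timelines: build a reference by permuting frames
    ref <- net
    ref$edges$timeline <- lapply(seq_along(ref$edges$timeline), function(i) {
      tl <- net$edges$timeline[[i]]
      withr::with_seed(seed + i, sample(tl))  # marginals kept, coupling broken
    })
    fwd <- dncf(net, ref)
    bwd <- dncf(ref, net)
    expect_equal(unclass(fwd), -unclass(bwd), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a planted coupled hub attains the top NCF rank", {
  hub <- generate_hub_network(n_nodes = 8, frames = 2000, coupling = 0.8,
                              seed = 99)
  s <- ncf(hub$network)
  expect_equal(names(which.max(s)), hub$hub)
})
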