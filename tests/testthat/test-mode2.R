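ref_nets <- split_by_sign(load_coefficient_matrix())

test_that("sign split sends every nonzero cell to exactly one network", {
  w <- matrix(c(-0.3, 0, 0.2, 0.5), 2,
              dimnames = list(c("f1", "f2"), c("o1", "o2")))
  nets <- split_by_sign(w)
  expect_equal(nrow(nets$protection$edges), 1L)
  expect_equal(nrow(nets$risk$edges), 2L)
  expect_equal(nets$protection$edges$factor, "f1")
  # zero matrix -> both empty
  z <- split_by_sign(matrix(0, 3, 2))
  expect_equal(nrow(z$protection$edges), 0L)
  expect_equal(nrow(z$risk$edges), 0L)
  expect_error(split_by_sign(matrix(c(1, NA), 1, 2)), "finite")

  # reference matrix: 21 protection and 23 risk edges
  expect_equal(nrow(ref_nets$protection$edges), 21L)
  expect_equal(nrow(ref_nets$risk$edges), 23L)
  # the all-risk factor promotes violence in every sphere
  other <- "Other networks"
  expect_equal(sum(ref_nets$protection$edges$factor == other), 0L)
  expect_equal(sum(ref_nets$risk$edges$factor == other), 4L)
})

test_that("geodesics honor bipartite parity and the unreachable rule", {
  d <- geodesics(ref_nets$protection)
  n1 <- 11L
  # cross-mode finite distances odd, within-mode even
  cross <- d[1:n1, (n1 + 1):15]
  expect_true(all(cross %% 2 == 1 | cross == max(d)))
  within <- d[1:n1, 1:n1][upper.tri(matrix(0, n1, n1))]
  expect_true(all(within %% 2 == 0 | within == max(d)))
  # max finite distance is 4, so unreachable pairs (the isolate) get 5
  expect_equal(max(d[d < max(d)]), 4)
  expect_equal(max(d), 5)
  expect_true(all(d["Other networks", colnames(d) != "Other networks"] == 5))
  expect_true(all(diag(d) == 0))

  # single edge (a, b) plus isolate c: d(a,b)=1, d to the isolate = 2
  w <- matrix(c(-1, 0), 2, 1, dimnames = list(c("a", "c"), "b"))
  ds <- geodesics(split_by_sign(w)$protection)
  expect_equal(ds["a", "b"], 1)
  expect_equal(ds["a", "c"], 2)
  expect_equal(ds["b", "c"], 2)

  # alternative convention: unreachable = node count
  ds2 <- geodesics(split_by_sign(w)$protection, unreachable = "order")
  expect_equal(ds2["a", "c"], 3)

  # edgeless network: all off-diagonal distances 1, with a message
  expect_message(dz <- geodesics(split_by_sign(matrix(0, 2, 2))$protection),
                 "no edges")
  expect_true(all(dz[row(dz) != col(dz)] == 1))
})

test_that("two-mode degree counts direct ties over the opposite mode", {
  deg_p <- two_mode_degree(ref_nets$protection)
  expect_equal(unname(deg_p["Neighborhood networks"]), 1.00)
  expect_equal(unname(deg_p["partner"]), 6 / 11)
  expect_equal(unname(deg_p["Other networks"]), 0)
  # factor degrees are multiples of 1/4, outcome degrees of 1/11
  expect_true(all(deg_p[1:11] * 4 == round(deg_p[1:11] * 4)))
  expect_true(all(abs(deg_p[12:15] * 11 - round(deg_p[12:15] * 11)) < 1e-12))

  # complementarity: every cell nonzero, so protection + risk degree = 1
  deg_r <- two_mode_degree(ref_nets$risk)
  expect_equal(unname(deg_p[1:11] + deg_r[1:11]), rep(1, 11))
})

test_that("two-mode closeness matches the published normalization", {
  clo_p <- two_mode_closeness(ref_nets$protection)
  expect_equal(unname(clo_p["Neighborhood networks"]), 24 / 27)
  expect_equal(unname(clo_p["Other networks"]), 24 / 70)
  clo_r <- two_mode_closeness(ref_nets$risk)
  expect_equal(unname(round(clo_r["Socio-economic level"], 2)), 0.62)
})

test_that("closeness equals the Floyd-Warshall oracle on random graphs", {
  set.seed(77)
  for (rep in 1:200) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:(12 - n1), 1)
    net <- random_mode_two(n1, n2, p_edge = stats::runif(1, 0.1, 0.6))
    d_oracle <- fw_distances(net)
    numer <- c(rep(n2 + 2 * (n1 - 1), n1), rep(n1 + 2 * (n2 - 1), n2))
    clo_oracle <- numer / rowSums(d_oracle)
    suppressMessages(
      expect_equal(unname(two_mode_closeness(net)), unname(clo_oracle)))
  }
})

test_that("adding an edge never hurts degree or lengthens finite paths", {
  set.seed(13)
  for (rep in 1:25) {
    net <- random_mode_two(4, 3, p_edge = 0.35)
    absent <- expand.grid(factor = net$mode_a, outcome = net$mode_b,
                          stringsAsFactors = FALSE)
    key <- paste(net$edges$factor, net$edges$outcome)
    absent <- absent[!paste(absent$factor, absent$outcome) %in% key, ]
    if (nrow(absent) == 0 || nrow(net$edges) == 0) next
    add <- absent[sample(nrow(absent), 1), ]
    net2 <- net
    net2$edges <- rbind(net$edges, add)
    expect_true(all(two_mode_degree(net2) >= two_mode_degree(net)))
    suppressMessages({
      d1 <- geodesics(net); d2 <- geodesics(net2)
    })
    fin1 <- d1 < max(d1) | d1 == 0
    expect_true(all(d2[fin1] <= d1[fin1]))
  }
})

test_that("centrality tables reproduce every published cell", {
  # protection network: all 30 printed degree/closeness values
  tab_p <- centrality_table(ref_nets$protection)
  expected_p <- data.frame(
    node = c("Neighborhood networks", "Socio-economic level",
             "Family networks", "Sexual stereotypes",
             "Family similar networks", "Religious org. networks",
             "Educational level", "Friend networks", "Economic dependence",
             "Partner educational level", "Other networks",
             "partner", "educational", "work", "public"),
    degree = c(1.00, 0.75, 0.75, 0.75, 0.50, 0.50, 0.25, 0.25, 0.25, 0.25,
               0.00, 0.55, 0.55, 0.45, 0.36),
    closeness = c(0.89, 0.77, 0.77, 0.77, 0.69, 0.65, 0.59, 0.59, 0.59,
                  0.53, 0.34, 0.59, 0.59, 0.55, 0.52))
  got <- tab_p[match(expected_p$node, tab_p$node), ]
  expect_equal(got$degree, expected_p$degree)
  expect_equal(got$closeness, expected_p$closeness)

  # risk network: all 30 printed values
  tab_r <- centrality_table(ref_nets$risk)
  expected_r <- data.frame(
    node = c("Other networks", "Educational level", "Friend networks",
             "Economic dependence", "Partner educational level",
             "Family similar networks", "Religious org. networks",
             "Socio-economic level", "Family networks", "Sexual stereotypes",
             "Neighborhood networks",
             "public", "work", "partner", "educational"),
    degree = c(1.00, 0.75, 0.75, 0.75, 0.75, 0.50, 0.50, 0.25, 0.25, 0.25,
               0.00, 0.64, 0.55, 0.45, 0.45),
    closeness = c(0.89, 0.83, 0.83, 0.83, 0.69, 0.65, 0.65, 0.62, 0.62,
                  0.62, 0.34, 0.63, 0.59, 0.55, 0.55))
  got_r <- tab_r[match(expected_r$node, tab_r$node), ]
  expect_equal(got_r$degree, expected_r$degree)
  expect_equal(got_r$closeness, expected_r$closeness)

  # layout: factors sorted by degree then closeness, outcomes after
  expect_equal(tab_p$mode, c(rep("factor", 11), rep("outcome", 4)))
  expect_true(!is.unsorted(rev(tab_p$degree_raw[1:11])))

  # empty network: zero degrees, degenerate closeness, no crash
  suppressMessages(
    empty <- centrality_table(split_by_sign(matrix(0, 2, 2))$protection))
  expect_true(all(empty$degree == 0))
  expect_equal(nrow(empty), 4L)
})
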