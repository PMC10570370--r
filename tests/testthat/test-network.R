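# Molecular network construction and summary statistics.

mk_net_ann <- function(formulas) {
  cbind(data.frame(formula = formulas), parse_formula(formulas))
}

test_that("edges join exactly the pairs differing by a reaction delta", {
  ann <- mk_net_ann(c("C2H4O2", "C4H6O2", "C2H4OS"))
  net <- build_network(ann)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 1)
  e <- igraph::as_data_frame(net)
  expect_setequal(unlist(e[c("from", "to")]), c("C2H4O2", "C4H6O2"))
  expect_equal(e$transformation, "c2h2_addition")
  # no self loops, undirected
  expect_false(igraph::any_loop(net))
  expect_false(igraph::is_directed(net))
})

test_that("edge order is invariant under annotation permutation", {
  forms <- c("C2H4O2", "C4H6O2", "C4H6O3", "C5H8O4", "C3H4O2")
  n1 <- build_network(mk_net_ann(forms))
  n2 <- build_network(mk_net_ann(rev(forms)))
  e1 <- igraph::as_data_frame(n1)
  e2 <- igraph::as_data_frame(n2)
  canon <- function(e) {
    k <- paste(pmin(e$from, e$to), pmax(e$from, e$to), e$transformation)
    sort(k)
  }
  expect_identical(canon(e1), canon(e2))
})

test_that("every edge's mass difference equals its transformation mass", {
  run <- noiseless_run()
  net <- run$network
  e <- igraph::as_data_frame(net)
  if (nrow(e)) {
    tr <- transformations()
    m_from <- monoisotopic_mass(parse_formula(e$from))
    m_to <- monoisotopic_mass(parse_formula(e$to))
    dm <- abs(m_to - m_from)
    expect_true(all(abs(dm - tr$delta_mass[match(e$transformation, tr$name)])
                    < 1e-9))
  }
})

test_that("connectivity fraction counts nodes with at least one edge", {
  ann <- mk_net_ann(c("C2H4O2", "C4H6O2", "C9H10O"))
  expect_equal(connectivity_fraction(build_network(ann)), 100 * 2 / 3,
               tolerance = 1e-10)
  chain <- mk_net_ann(c("C2H4O2", "C4H6O2", "C6H8O2"))
  expect_equal(connectivity_fraction(build_network(chain)), 100)
  isolated <- mk_net_ann(c("C2H4O2", "C9H10O", "C11H12O5"))
  expect_equal(connectivity_fraction(build_network(isolated)), 0)
  expect_error(connectivity_fraction(build_network(mk_net_ann(character()))),
               "empty")
})

test_that("first detection time is the earliest passing timepoint", {
  det <- rbind(c(FALSE, TRUE, TRUE), c(TRUE, FALSE, FALSE))
  expect_equal(first_detection_time(det, c(2, 24, 168)), c(24, 2))
  expect_error(first_detection_time(rbind(c(FALSE, FALSE, FALSE)),
                                    c(2, 24, 168)), "never detected")
})

test_that("sulfur-class shares reproduce counting arithmetic", {
  ann <- mk_net_ann(c(sprintf("C%dH%dO2S3", 5:10, 6:11),
                      sprintf("C%dH%dO2S", 5:12, 6:13),
                      sprintf("C%dH%dO3", 5:9, 6:10)))
  det <- matrix(TRUE, nrow(ann), 1)
  sh <- sulfur_class_shares(ann, det, 2)
  s3 <- sh$sulfur[sh$sulfur$s == 3, ]
  expect_equal(s3$n, 6)
  expect_equal(s3$pct, 100 * 6 / 14)
  # oxygen shares among sulfur-free annotations
  o3 <- sh$oxygen[sh$oxygen$o == 3, ]
  expect_equal(o3$n, 5)
  expect_equal(o3$pct, 100)
  # a timepoint without S-annotations contributes no sulfur rows
  det2 <- cbind(det, FALSE)
  sh2 <- sulfur_class_shares(ann, det2, c(2, 24))
  expect_false(24 %in% sh2$sulfur$timepoint)
})

test_that("graphml export round-trips node and edge attributes", {
  ann <- mk_net_ann(c("C2H4O2", "C4H6O2"))
  net <- build_network(ann)
  f <- tempfile(fileext = ".graphml")
  export_network_graphml(net, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_setequal(igraph::V(back)$name, c("C2H4O2", "C4H6O2"))
  expect_equal(igraph::E(back)$transformation, "c2h2_addition")
})
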