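test_that("connectance and link density follow their closed forms", {
  expect_equal(connectance(5, 5), 0.2)
  expect_equal(connectance(106, 1049), 1049 / 106^2)
  expect_equal(round(connectance(106, 1049), 4), 0.0934)
  expect_equal(round(connectance(82, 637), 4), 0.0947)
  expect_equal(round(link_density(106, 1049), 2), 9.90)
  expect_equal(round(link_density(82, 637), 2), 7.77)
  expect_equal(round(link_density(106, 1049) / link_density(82, 637), 2), 1.27)
  expect_equal(link_density(10, 0), 0)
  expect_error(connectance(0, 0), "undefined")
  expect_error(link_density(0, 0), "undefined")
})

test_that("a three-node chain is classified and levelled correctly", {
  w <- monthly_web(1, c("a", "b", "c"),
                   data.frame(resource = c("a", "b"), consumer = c("b", "c")))
  tl <- trophic_levels(w)
  expect_equal(unname(tl), c(1, 2, 3))
  pos <- trophic_positions(w)
  expect_equal(pos$class, c("basal", "intermediate", "top"))
  dv <- descriptor_vector(w)
  expect_equal(unname(dv["S"]), 3)
  expect_equal(unname(dv["L"]), 2)
  expect_equal(unname(dv["C"]), 2 / 9)
  expect_equal(unname(dv[c("frac_top", "frac_intermediate", "frac_basal")]),
               rep(1 / 3, 3))
})

test_that("omnivory, cannibalism and isolated nodes follow the definitions", {
  # d eats a basal (TL 1) and a TL-2 node -> omnivore
  w <- monthly_web(1, c("a", "b", "d"),
                   data.frame(resource = c("a", "a", "b"),
                              consumer = c("b", "d", "d")))
  pos <- trophic_positions(w)
  expect_true(pos$omnivore[pos$node == "d"])
  expect_false(pos$omnivore[pos$node == "b"])

  # predator eating two TL-2 prey sits at TL 3, not an omnivore
  w2 <- monthly_web(1, c("a", "b1", "b2", "c"),
                    data.frame(resource = c("a", "a", "b1", "b2"),
                               consumer = c("b1", "b2", "c", "c")))
  expect_equal(unname(trophic_levels(w2)["c"]), 3)
  expect_false(trophic_positions(w2)$omnivore[4])

  # isolated node: classified basal, message raised
  w3 <- monthly_web(1, c("a", "b", "iso"),
                    data.frame(resource = "a", consumer = "b"))
  expect_message(pos3 <- trophic_positions(w3), "isolated")
  expect_equal(pos3$class[pos3$node == "iso"], "basal")
  expect_equal(sum(pos3$class == "basal") + sum(pos3$class == "top") +
                 sum(pos3$class == "intermediate"), 3)

  # self-link: counts as cannibal, excluded from top/basal classification
  w4 <- monthly_web(1, c("a", "b"),
                    data.frame(resource = c("a", "b"), consumer = c("b", "b")))
  pos4 <- trophic_positions(w4)
  expect_true(pos4$cannibal[pos4$node == "b"])
  expect_equal(pos4$class[pos4$node == "b"], "top")
  expect_equal(unname(trophic_levels(w4)["b"]), 2)  # self-link ignored
})

test_that("linear-system trophic levels match long fixed-point iteration", {
  set.seed(42)
  for (rep in 1:5) {
    w <- rand_layered_web(c(5, 15, 20, 10), p = 0.3)
    tl <- trophic_levels(w)
    tl_it <- oracle_tl(w)
    expect_lt(max(abs(tl - tl_it)), 1e-8)
  }
})

test_that("trophic levels flag consumers with no path to a basal node", {
  w <- monthly_web(1, c("a", "x", "y"),
                   data.frame(resource = c("x", "y"), consumer = c("y", "x")))
  expect_warning(tl <- trophic_levels(w), "no path")
  expect_true(is.na(tl["x"]) && is.na(tl["y"]))
  expect_equal(unname(tl["a"]), 1)
})

test_that("a complete 4-node digraph without self-links has C = 0.75", {
  nodes <- letters[1:4]
  pairs <- expand.grid(resource = nodes, consumer = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$resource != pairs$consumer, ]
  w <- monthly_web(1, nodes, pairs)
  dv <- suppressWarnings(descriptor_vector(w))
  expect_equal(unname(dv["C"]), 12 / 16)
})

test_that("adding one link raises C by exactly 1/S^2 and L by 1", {
  set.seed(7)
  for (rep in 1:20) {
    w <- rand_web(sample(4:9, 1), p = 0.3)
    absent <- setdiff(
      as.vector(outer(w$nodes, w$nodes, paste, sep = " -> ")),
      link_set(w))
    if (!length(absent)) next
    pick <- strsplit(sample(absent, 1), " -> ", fixed = TRUE)[[1]]
    w2 <- monthly_web(w$month, w$nodes,
                      rbind(w$links[, c("resource", "consumer")],
                            data.frame(resource = pick[1], consumer = pick[2])))
    d1 <- suppressWarnings(descriptor_vector(w))
    d2 <- suppressWarnings(descriptor_vector(w2))
    expect_equal(unname(d2["S"]), unname(d1["S"]))
    expect_equal(unname(d2["L"]), unname(d1["L"]) + 1)
    expect_equal(unname(d2["C"] - d1["C"]), 1 / unname(d1["S"])^2)
  }
})

test_that("descriptors are invariant to node relabelling", {
  set.seed(8)
  w <- rand_web(8, p = 0.35)
  perm <- sample(w$nodes)
  names(perm) <- w$nodes
  w2 <- monthly_web(w$month, unname(perm[w$nodes]),
                    data.frame(resource = unname(perm[w$links$resource]),
                               consumer = unname(perm[w$links$consumer])))
  d1 <- suppressWarnings(descriptor_vector(w))
  d2 <- suppressWarnings(descriptor_vector(w2))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("the panel fractions sum to one and the matrix has no gaps", {
  com <- generate_community(synth_config(seed = 14))
  iy <- suppressWarnings(pool_idealized_year(com$samples))
  webs <- build_monthly_webs(iy, com$links, com$taxa)
  dm <- descriptor_matrix(webs)
  expect_equal(nrow(dm), 12)
  expect_false(anyNA(dm))
  sums <- dm$frac_top + dm$frac_intermediate + dm$frac_basal
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(dm$C >= 0 & dm$C <= 1))
  expect_true(all(dm$mean_TL >= 1))
})

test_that("summer months carry more links than winter months", {
  cfg <- synth_config(seed = 15)
  com <- generate_community(cfg)
  iy <- suppressWarnings(pool_idealized_year(com$samples))
  dm <- descriptor_matrix(build_monthly_webs(iy, com$links, com$taxa))
  winter <- dm$L[cfg$winter_months]
  summer <- dm$L[setdiff(1:12, cfg$winter_months)]
  expect_gt(mean(summer), mean(winter))
})
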