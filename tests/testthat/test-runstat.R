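# Direct-arithmetic oracle: statistic sums computed straight from the
# store matrices, bypassing the streaming driver.
oracle_d_sums <- function(st, h1, h2, h3, h4, subset = NULL) {
  i <- match(c(h1, h2, h3, h4), st$pops$name)
  usable <- rowSums(st$total[, i, drop = FALSE] < 1L) == 0L
  if (!is.null(subset)) usable <- usable & subset
  p <- st$countA[usable, i] / st$total[usable, i]
  k <- site_d(p[, 1], p[, 2], p[, 3], p[, 4])
  list(num = k$num, den = k$den, usable = usable)
}

test_that("D with duplicated slot populations is exactly zero", {
  st <- fixture_store_random(300, 4, seed = 2)
  r <- run_stat(st, stat_request("d", h1 = "Pop1", h2 = "Pop1",
                                 h3 = "Pop2", h4 = "Pop3"))
  expect_equal(r$estimate, 0)
  expect_equal(r$z, 0)
})

test_that("corrected f4 at c = 0 equals plain f4 bit for bit", {
  st <- fixture_store_random(400, 5, seed = 3)
  f4 <- run_stat(st, stat_request("f4", h1 = "Pop1", h2 = "Pop2",
                                  h3 = "Pop3", h4 = "Pop4"))
  grid <- run_stat(st, stat_request("corrected_f4", h1 = "Pop1",
                                    h2 = "Pop2", h3 = "Pop3", h4 = "Pop4",
                                    x = "Pop5", minp = 0, maxp = 0.1,
                                    pstep = 0.05))
  expect_identical(grid$estimate[grid$c == 0], f4$estimate)
  expect_identical(grid$se[grid$c == 0], f4$se)
  expect_identical(grid$n_sites[grid$c == 0], f4$n_sites)
})

test_that("corrected-f4 usable set conditions on the proxy population", {
  st <- fixture_store_random(400, 5, seed = 4)
  st$total[1:50, 5] <- 0L  # proxy missing at 50 sites
  f4_all <- run_stat(st, stat_request("f4", h1 = "Pop1", h2 = "Pop2",
                                      h3 = "Pop3", h4 = "Pop4"))
  grid <- run_stat(st, stat_request("corrected_f4", h1 = "Pop1",
                                    h2 = "Pop2", h3 = "Pop3", h4 = "Pop4",
                                    x = "Pop5", minp = 0, maxp = 0,
                                    pstep = 0.025))
  expect_identical(grid$n_sites[1], f4_all$n_sites - 50)
})

test_that("enhanced D equals plain D on the pre-filtered site subset", {
  st <- fixture_store_random(600, 5, seed = 6)
  # make the ascertainer fixed-A at a third of sites
  set.seed(60)
  fixed <- runif(600) < 1 / 3
  st$countA[, 5] <- ifelse(fixed, st$total[, 5], pmin(st$countA[, 5],
                                                      st$total[, 5] - 1L))
  scheme <- list(list(pop = "Pop5", fixed = "A", min_total = 1L))
  enh <- run_stat(st, stat_request("enhanced_d", h1 = "Pop1", h2 = "Pop2",
                                   h3 = "Pop3", h4 = "Pop4",
                                   ascertainment = scheme))
  # oracle: drop non-ascertained sites, then run plain D
  st2 <- st
  keep <- st$countA[, 5] == st$total[, 5] & st$total[, 5] >= 1L
  st2$sites <- st2$sites[keep, , drop = FALSE]
  st2$countA <- st2$countA[keep, , drop = FALSE]
  st2$total <- st2$total[keep, , drop = FALSE]
  plain <- run_stat(st2, stat_request("d", h1 = "Pop1", h2 = "Pop2",
                                      h3 = "Pop3", h4 = "Pop4"))
  expect_equal(enh$estimate, plain$estimate, tolerance = 1e-14)
  expect_equal(enh$se, plain$se, tolerance = 1e-14)
  expect_identical(enh$n_sites, plain$n_sites)
})

test_that("MAC-stratified D matches per-stratum oracles and pools to plain D", {
  st <- fixture_store_random(800, 4, seed = 8)
  tab <- run_stat(st, stat_request("mac_d", h1 = "Pop1", h2 = "Pop2",
                                   h3 = "Pop3", h4 = "Pop4",
                                   strat_pop = "Pop1"))
  plain <- run_stat(st, stat_request("d", h1 = "Pop1", h2 = "Pop2",
                                     h3 = "Pop3", h4 = "Pop4"))
  mac <- mac_stratum(st$countA[, 1], st$total[, 1])
  num_tot <- 0; den_tot <- 0; n_tot <- 0L
  for (s in unique(tab$stratum)) {
    o <- oracle_d_sums(st, "Pop1", "Pop2", "Pop3", "Pop4",
                       subset = mac == s)
    row <- tab[tab$stratum == s, ]
    expect_equal(row$estimate, sum(o$num) / sum(o$den), tolerance = 1e-12)
    expect_equal(row$n_sites, sum(o$usable))
    num_tot <- num_tot + sum(o$num)
    den_tot <- den_tot + sum(o$den)
    n_tot <- n_tot + sum(o$usable)
  }
  # strata partition the usable sites; pooled sums give the plain D
  expect_equal(sum(tab$n_sites), plain$n_sites)
  expect_equal(num_tot / den_tot, plain$estimate, tolerance = 1e-12)
})

test_that("f3 correction is refused for pseudo-haploid targets", {
  st <- fixture_store_random(100, 3, seed = 10)
  st <- merge_counts(st, "Ancient", rep(c("A", "B"), 50))
  expect_error(run_stat(st, stat_request("f3", target = "Ancient",
                                         h1 = "Pop1", h2 = "Pop2",
                                         correct = TRUE)),
               "pseudo-haploid")
  r <- run_stat(st, stat_request("f3", target = "Pop1", h1 = "Pop2",
                                 h2 = "Ancient", correct = TRUE))
  expect_true(is.finite(r$estimate))
})

test_that("enumeration yields one row per candidate in store order", {
  st <- fixture_store_random(200, 4, seed = 12)
  tab <- enumerate_fixed(st, "f3",
                         list(h1 = "Pop1", target = "Pop2"), "h2")
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$h2, c("Pop3", "Pop4"))
  tab_d <- enumerate_fixed(st, "d",
                           list(h1 = "Pop1", h2 = "Pop2", h4 = "Pop4"),
                           "h3")
  expect_identical(tab_d$h3, "Pop3")
  expect_error(enumerate_fixed(st, "d",
                               list(h1 = "Pop1", h2 = "Pop2",
                                    h4 = "Pop4"),
                               "h3", exclude = "Pop3"),
               "no candidate")
  expect_error(enumerate_fixed(st, "d",
                               list(h1 = "Pop1", h2 = "Pop1",
                                    h4 = "Pop4"), "h3"),
               "distinct")
})

test_that("parallel and serial enumeration produce identical tables", {
  st <- fixture_store_random(400, 8, seed = 14)
  serial <- enumerate_fixed(st, "d",
                            list(h1 = "Pop1", h2 = "Pop2", h4 = "Pop3"),
                            "h3")
  par <- enumerate_fixed(st, "d",
                         list(h1 = "Pop1", h2 = "Pop2", h4 = "Pop3"),
                         "h3", nthr = 4L)
  expect_identical(par, serial)
})

test_that("each enumerated row is reproduced by a single run_stat call", {
  st <- fixture_store_random(300, 5, seed = 16)
  tab <- enumerate_fixed(st, "d",
                         list(h1 = "Pop1", h2 = "Pop2", h4 = "Pop3"),
                         "h3")
  for (i in seq_len(nrow(tab))) {
    r <- run_stat(st, stat_request("d", h1 = "Pop1", h2 = "Pop2",
                                   h3 = tab$h3[i], h4 = "Pop3"))
    expect_identical(tab$estimate[i], r$estimate)
    expect_identical(tab$se[i], r$se)
  }
})

test_that("transversion restriction drops transition sites from n_sites", {
  st <- fixture_store_small()
  r_all <- run_stat(st, stat_request("dist", h1 = "P1", h2 = "P2"))
  r_tv <- run_stat(st, stat_request("dist", h1 = "P1", h2 = "P2",
                                    transversions_only = TRUE))
  expect_identical(r_all$n_sites, 5)   # snp4 missing in P2
  expect_identical(r_tv$n_sites, 3)    # minus snp2 (C/T), snp5 (G/A)
})

test_that("unknown slot populations fail with the available names listed", {
  st <- fixture_store_random(50, 3, seed = 18)
  expect_error(run_stat(st, stat_request("dist", h1 = "Pop1",
                                         h2 = "Nope")),
               "available")
})
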