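test_that("problem construction keeps core rows and known proteins only", {
  ds <- complexome_dataset(data.frame(
    complex = c("J", "J", "J", "J"),
    protein = c("x", "y", "z", "w"),
    role = c("core", "core", "attachment", "core")))
  ab <- abundance_table(data.frame(protein = c("x", "y", "w"),
                                   condition = "YEPD",
                                   abundance = c(5, 3, NA)))
  pb <- build_abundance_problem(ds, ab, "YEPD")
  expect_setequal(pb$K, c("x", "y"))
  expect_false("z" %in% rownames(pb$S))        # attachments never enter S
  expect_true("w" %in% rownames(pb$S))         # unknown core stays imputable
  expect_equal(Matrix::nnzero(pb$S[pb$K, ]), 2)

  att_only <- complexome_dataset(data.frame(complex = "J", protein = "z",
                                            role = "attachment"))
  expect_error(build_abundance_problem(att_only, ab, "YEPD"),
               "nothing to estimate")
})

test_that("the LP solves the worked toys exactly", {
  ds <- complexome_dataset(data.frame(complex = "J",
                                      protein = c("x", "y"), role = "core"))
  ab <- abundance_table(toy_abundance_df(c("x", "y"), c(5, 3)))
  sol <- solve_abundance(build_abundance_problem(ds, ab, "YEPD"))
  expect_equal(unname(sol$c["J"]), 3)
  expect_equal(sol$DA, 2)

  ds2 <- complexome_dataset(data.frame(complex = c("J1", "J2", "J2"),
                                       protein = c("x", "x", "y"),
                                       role = "core"))
  ab2 <- abundance_table(toy_abundance_df(c("x", "y"), c(4, 1)))
  sol2 <- solve_abundance(build_abundance_problem(ds2, ab2, "YEPD"))
  expect_equal(unname(sol2$c[c("J1", "J2")]), c(3, 1))
  expect_equal(sol2$DA, 0)

  # a complex whose cores are all unknown is undetermined with c = 0
  ds3 <- complexome_dataset(data.frame(complex = c("J", "K"),
                                       protein = c("x", "u"),
                                       role = "core"))
  sol3 <- solve_abundance(build_abundance_problem(ds3, ab, "YEPD"))
  expect_equal(unname(sol3$c["K"]), 0)
  expect_equal(sol3$undetermined, "K")
})

test_that("imputation applies the ideal balance to unknown proteins", {
  ds <- complexome_dataset(data.frame(
    complex = c("J1", "J2", "J2", "J2"),
    protein = c("x", "x", "y", "z"), role = "core"))
  ab <- abundance_table(toy_abundance_df(c("x", "y"), c(4, 1)))
  sol <- solve_abundance(build_abundance_problem(ds, ab, "YEPD"))
  imp <- impute_abundance(sol, ds)
  expect_equal(unname(imp["z"]), 1)            # c_J2 at the solved optimum

  # linearity across two complexes
  ds2 <- complexome_dataset(data.frame(
    complex = c("J1", "J1", "J2", "J2", "J1", "J2"),
    protein = c("x", "q", "y", "q", "m", "m"), role = "core"))
  ab2 <- abundance_table(toy_abundance_df(c("x", "y"), c(3, 1)))
  sol2 <- solve_abundance(build_abundance_problem(ds2, ab2, "YEPD"))
  imp2 <- impute_abundance(sol2, ds2)
  expect_equal(unname(imp2["q"]),
               unname(sol2$c["J1"] + sol2$c["J2"]))

  # protein only in an undetermined complex: 0 with provenance flag
  ds3 <- complexome_dataset(data.frame(complex = c("J", "K"),
                                       protein = c("x", "u"),
                                       role = "core"))
  ab3 <- abundance_table(toy_abundance_df("x", 5))
  sol3 <- solve_abundance(build_abundance_problem(ds3, ab3, "YEPD"))
  imp3 <- impute_abundance(sol3, ds3)
  expect_equal(unname(imp3["u"]), 0)
  expect_equal(unname(attr(imp3, "provenance")["u"]), "undetermined")
})

test_that("LP optima match vertex enumeration on random instances", {
  for (seed in 1:30) {
    inst <- random_lp_instance(seed)
    ds <- lp_instance_dataset(inst)
    ab <- abundance_table(toy_abundance_df(inst$proteins, inst$p))
    sol <- solve_abundance(build_abundance_problem(ds, ab, "YEPD"))
    w <- colSums(inst$S)
    oracle <- lp_vertex_oracle(inst$S, inst$p, w)
    expect_equal(sum(inst$p) - oracle$value, sol$DA, tolerance = 1e-6)
    # availability constraints hold at the optimum
    expect_true(all(sol$slack >= -1e-8))
    expect_equal(sol$DA, sum(sol$slack), tolerance = 1e-6)
  }
})

test_that("adding a complex never increases the optimal leftover", {
  for (seed in 31:40) {
    inst <- random_lp_instance(seed)
    ab <- abundance_table(toy_abundance_df(inst$proteins, inst$p))
    base <- solve_abundance(build_abundance_problem(
      lp_instance_dataset(inst), ab, "YEPD"))
    set.seed(1000 + seed)
    extra <- inst
    newcol <- rbinom(length(inst$proteins), 1, 0.5)
    if (sum(newcol) == 0) newcol[1] <- 1
    extra$S <- cbind(inst$S, newcol)
    extra$complexes <- c(inst$complexes, "Jnew")
    more <- solve_abundance(build_abundance_problem(
      lp_instance_dataset(extra), ab, "YEPD"))
    expect_lte(more$DA, base$DA + 1e-8)
  }
})

test_that("optimal-face intervals bracket the reported copy numbers", {
  # two complexes sharing one budget: the optimum is degenerate
  ds <- complexome_dataset(data.frame(complex = c("J1", "J2"),
                                      protein = c("x", "x"), role = "core"))
  ab <- abundance_table(toy_abundance_df("x", 6))
  sol <- solve_abundance(build_abundance_problem(ds, ab, "YEPD"),
                         intervals = TRUE)
  iv <- sol$intervals
  expect_equal(iv$min, c(0, 0), tolerance = 1e-6)
  expect_equal(iv$max, c(6, 6), tolerance = 1e-6)
  expect_true(all(sol$c[iv$complex] >= iv$min - 1e-8 &
                    sol$c[iv$complex] <= iv$max + 1e-8))
})

test_that("category ratio tables classify and overlap as specified", {
  ds <- complexome_dataset(data.frame(complex = c("A", "B"),
                                      protein = c("x", "y"), role = "core"))
  mk_sol <- function(vals) structure(
    list(c = vals, DA = 0, slack = numeric(0), undetermined = character(0),
         condition = "any", K = character(0)), class = "abundance_solution")
  fsol <- structure(list(
    assignments = data.frame(complex = c("A", "A", "B"),
                             code = c("01.01.01", "02.01.01", "01.02.01"),
                             confidence = "HC", sources = ""),
    m_star = c(), variant = "min_complexes"), class = "function_solution")
  sd <- mk_sol(c(A = 6, B = 1)); yepd <- mk_sol(c(A = 5, B = 0))
  tab <- abundance_ratio_by_category(sd, yepd, fsol, level = 1)
  # boundary ratio 1.2 goes to the middle class; B is excluded (c_YEPD = 0)
  expect_equal(attr(tab, "n_excluded"), 1L)
  expect_equal(tab$mean_ratio[tab$category == "01"], 1.2)
  expect_equal(tab$n_mid[tab$category == "01"], 1)
  expect_equal(tab$n_up[tab$category == "01"], 0)
  # complex A carries two top-level categories: it appears in both rows
  expect_setequal(tab$category, c("01", "02"))
  expect_equal(tab$n_complexes, c(1, 1))
})
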