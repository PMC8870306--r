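test_that("simulated cohorts realize the requested level mix", {
  study <- cached_study()
  freq <- prop.table(table(study$clinical$npi_level))
  expect_true(all(abs(freq - 0.25) <= 0.05))
  expect_equal(nrow(study$clinical), 400L)
})

test_that("labels are always derived from simulated size, nodes and grade", {
  cl <- cached_study()$clinical
  rederived <- npi_level(compute_npi(cl$tumor_size_cm,
                                     node_category(cl$positive_nodes),
                                     cl$grade))
  expect_identical(as.character(rederived), as.character(cl$npi_level))
})

test_that("censoring control works and relapse means are level-ordered", {
  cl0 <- simulate_clinical(simulation_config(n_samples = 120L,
                                             censoring_rate = 0, seed = 7L))
  expect_true(all(cl0$relapse_event))

  cl <- cached_study()$clinical
  means <- tapply(cl$relapse_time_months, cl$npi_level, mean)
  expect_gt(means[["I"]], means[["III"]])
  expect_gt(means[["II"]], means[["IV"]])
  expect_gt(means[["III"]], means[["IV"]])
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_study(simulation_config(n_samples = 60L, n_genes = 40L, seed = 9L))
  b <- simulate_study(simulation_config(n_samples = 60L, n_genes = 40L, seed = 9L))
  expect_identical(a$clinical, b$clinical)
  expect_identical(unclass(a$matrices$expression), unclass(b$matrices$expression))
  expect_identical(unclass(a$matrices$cna), unclass(b$matrices$cna))
  c2 <- simulate_study(simulation_config(n_samples = 60L, n_genes = 40L, seed = 10L))
  expect_false(identical(unclass(a$matrices$expression),
                         unclass(c2$matrices$expression)))
})

test_that("informative genes carry level-ordered signal in all three omics", {
  study <- cached_study()
  lev <- as.integer(study$clinical$npi_level)
  inf <- attr(study$matrices$expression, "informative_genes")
  expect_length(inf, 10L)

  for (g in inf[1:3]) {
    e <- log(unclass(study$matrices$expression)[g, ])
    expect_gt(mean(e[lev == 4]) - mean(e[lev == 1]), 3)  # 3 * effect_size / 2
    cn <- unclass(study$matrices$cna)[g, ]
    expect_gt(mean(cn[lev == 4]), mean(cn[lev == 1]))
  }
  # mRNA mirrors expression for informative genes
  r <- cor(log(unclass(study$matrices$expression)[inf[1], ]),
           log(unclass(study$matrices$mrna)[inf[1], ]))
  expect_gt(r, 0.9)
})

test_that("a null cohort (effect size 0) has no class-separable genes", {
  st <- simulate_study(simulation_config(n_samples = 200L, n_genes = 100L,
                                         effect_size = 0, seed = 21L))
  lev <- as.integer(st$clinical$npi_level)
  inf <- attr(st$matrices$expression, "informative_genes")
  x <- log(unclass(st$matrices$expression)[inf, , drop = FALSE])
  d <- apply(x, 1L, function(v) {
    (mean(v[lev == 4]) - mean(v[lev == 1])) /
      stats::sd(v)
  })
  expect_true(all(abs(d) < 4 / sqrt(sum(lev == 1))))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(level_mix = c(0.5, 0.5, 0.5, 0.5)))
  expect_error(simulation_config(n_informative = 50L, n_genes = 10L))
  expect_error(simulation_config(relapse_mean_months = c(50, 80, 100, 120)))
})
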