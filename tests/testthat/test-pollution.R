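test_that("index arithmetic matches hand-computed values", {
  expect_equal(contamination_factor(10, 4), 2.5)
  expect_equal(contamination_factor(7, 7), 1)
  expect_equal(ecological_risk(2, 30), 60)
  expect_equal(ecological_risk(3, 1), 3)
  expect_equal(nemerow_index(c(4, 2)), sqrt(12.5))
  expect_equal(nemerow_index(rep(2.7, 4)), 2.7)  # all-equal Cf collapses to Cf
  expect_error(contamination_factor(-1, 4), "finite and > 0")
  expect_error(nemerow_index(numeric(0)), "at least one")
})

test_that("RI equals brute-force summation and simple identities", {
  panel <- toy_panel()
  ref <- toy_background()
  ri <- risk_index(panel, ref)
  oracle <- vapply(seq_len(nrow(panel)), function(i) {
    s <- 0
    for (m in panel_metals(panel)) {
      s <- s + ref$tr[ref$metal == m] * panel[[m]][i] / ref$cn[ref$metal == m]
    }
    s
  }, numeric(1))
  expect_equal(ri$ri, oracle, tolerance = 1e-12)

  # all cs = cn gives RI = sum(Tr)
  flat <- metal_panel(tibble::tibble(site = "X", Cu = 24.4, Cd = 0.186, Zn = 66.5))
  expect_equal(risk_index(flat, ref)$ri, sum(ref$tr))

  # unknown metal is named in the error
  bad <- metal_panel(tibble::tibble(site = "X", Cu = 10, Hg = 1))
  expect_error(risk_index(bad, ref), "Hg")
})

test_that("indices obey their structural invariants", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      cf <- rexp(k) + 0.05
      pn <- nemerow_index(cf)
      expect_gte(pn, mean(cf) - 1e-12)
      expect_lte(pn, max(cf) + 1e-12)
    }
  })

  panel <- toy_panel()
  ref <- toy_background()
  scores <- assess_pollution(panel, ref)
  # er = tr * cf exactly; ri = sum er
  expect_equal(tidy(scores)$er, tidy(scores)$tr * tidy(scores)$cf)
  ri_sum <- tidy(scores) |> dplyr::group_by(site) |>
    dplyr::summarise(ri = sum(er))
  expect_equal(pollution_sites(scores)$ri,
               ri_sum$ri[match(pollution_sites(scores)$site, ri_sum$site)],
               tolerance = 1e-9)

  # scale invariance: multiplying cs and cn by the same factor changes nothing
  ref2 <- background_ref(dplyr::mutate(tibble::as_tibble(ref), cn = cn * 3.7))
  panel2 <- panel
  for (m in panel_metals(panel)) panel2[[m]] <- panel2[[m]] * 3.7
  s2 <- assess_pollution(metal_panel(panel2), ref2)
  expect_equal(pollution_sites(s2)$pn, pollution_sites(scores)$pn, tolerance = 1e-12)
  expect_equal(pollution_sites(s2)$ri, pollution_sites(scores)$ri, tolerance = 1e-12)

  # monotonicity: raising one concentration raises both indices
  panel3 <- panel
  panel3$Cd[1] <- panel3$Cd[1] * 1.5
  s3 <- assess_pollution(metal_panel(panel3), ref)
  expect_gt(pollution_sites(s3)$pn[1], pollution_sites(scores)$pn[1])
  expect_gt(pollution_sites(s3)$ri[1], pollution_sites(scores)$ri[1])
})

test_that("grade labels follow the published verbal scale", {
  expect_equal(classify_pn(13.18), "heavy")
  expect_equal(classify_pn(0.5), "clean")
  expect_equal(classify_pn(c(0.7, 0.9, 1.5, 2.5)),
               c("clean", "warning", "light", "moderate"))
  expect_equal(classify_ri(609.24), "very strong")
  expect_equal(classify_ri(c(100, 200, 450)), c("low", "moderate", "strong"))
})

test_that("a site dominating every metal ranks first on PN and RI", {
  panel <- metal_panel(tibble::tibble(site = c("top", "mid", "low"),
                                      Cu = c(300, 60, 30),
                                      Cd = c(3, 0.8, 0.3),
                                      Zn = c(400, 120, 70)))
  s <- assess_pollution(panel, toy_background())
  top <- pollution_sites(s)[pollution_sites(s)$site == "top", ]
  expect_equal(top$rank_pn, 1L)
  expect_equal(top$rank_ri, 1L)
  expect_equal(glance(s)$top_site, "top")
})

test_that("replicate panels support both aggregation modes", {
  sc <- generate_scenario(scenario_config(noise_sd = 0.2, n_taxa = 10,
                                          depth = 100), seed = 9)
  ref <- sc$background
  a <- assess_pollution(sc$panel, ref, mode = "mean_conc")
  b <- assess_pollution(sc$panel, ref, mode = "per_replicate")
  expect_false(any(c("pn_sd", "ri_sd") %in% names(pollution_sites(a))))
  expect_true(all(c("pn_sd", "ri_sd") %in% names(pollution_sites(b))))
  # RI is linear in concentrations, so site means agree across modes
  expect_equal(pollution_sites(a)$ri, pollution_sites(b)$ri, tolerance = 1e-9)
  # PN is convex, so replicate-mean PN is at least the mean-concentration PN
  expect_true(all(pollution_sites(b)$pn >= pollution_sites(a)$pn - 1e-9))
})

test_that("noise-free synthetic panels recover ground-truth PN and RI exactly", {
  sc <- generate_scenario(scenario_config(noise_sd = 0, n_taxa = 10, depth = 100),
                          seed = 3)
  s <- assess_pollution(sc$panel, sc$background)
  sites <- pollution_sites(s)
  ord <- match(sites$site, names(sc$truth$pn_true))
  expect_equal(sites$pn, unname(sc$truth$pn_true[ord]), tolerance = 1e-12)
  expect_equal(sites$ri, unname(sc$truth$ri_true[ord]), tolerance = 1e-12)
})
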