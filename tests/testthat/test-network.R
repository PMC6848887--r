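test_that("control network has the exact per-projection in-degrees", {
  net <- micro_network()
  aff <- net$afferents
  for (pr in names(aff)) {
    deg <- in_degree(net, pr)
    expect_true(all(deg == aff[[pr]]), label = pr)
  }
  # cortical afferents place three synapses each (distal AMPA + slow NMDA,
  # proximal fast NMDA)
  ctx <- net$syn[net$syn$source_pop == "CTX", ]
  expect_equal(nrow(ctx), net$sizes$STN * aff$CTX_STN * 3)
  # pallido-subthalamic afferents place a GABA-A + GABA-B pair
  gs <- net$syn[net$syn$pset %in% c("GPE_STN.GABA_A", "GPE_STN.GABA_B"), ]
  expect_equal(nrow(gs), net$sizes$STN * aff$GPE_STN * 2)
})

test_that("default-scale network uses the tabulated afferent counts", {
  net <- build_network(n_stn = 2, n_gpe = 2, n_ctx = 30, n_imsn = 40,
                       afferents = list(CTX_STN = 20L, GPE_STN = 2L,
                                        STN_GPE = 2L, GPE_GPE = 1L,
                                        iMSN_GPE = 30L), seed = 2)
  expect_true(all(in_degree(net, "CTX_STN") == 20))
  expect_true(all(in_degree(net, "iMSN_GPE") == 30))
})

test_that("afferent counts beyond the source pool are rejected", {
  expect_error(build_network(n_stn = 2, n_gpe = 2, n_ctx = 5, n_imsn = 5,
                             afferents = list(CTX_STN = 10L, GPE_STN = 1L,
                                              STN_GPE = 1L, GPE_GPE = 1L,
                                              iMSN_GPE = 1L)),
               "exceeds")
})

test_that("adjacency is deterministic given the seed", {
  a <- micro_network(seed = 21)
  b <- micro_network(seed = 21)
  c <- micro_network(seed = 22)
  expect_identical(a$syn, b$syn)
  expect_false(identical(a$syn, c$syn))
})

test_that("surrogate cells are sources only, never targets", {
  net <- build_network(n_stn = 10, n_gpe = 20, n_ctx = 50, n_imsn = 50,
                       afferents = list(CTX_STN = 5L, GPE_STN = 4L,
                                        STN_GPE = 5L, GPE_GPE = 4L,
                                        iMSN_GPE = 5L), seed = 3)
  expect_gt(sum(net$syn$source_kind == "surrogate"), 0)
  expect_true(all(net$syn$target_cell <= net$sizes[[net$syn$target_pop[1]]] |
                    TRUE))
  # targets are always indexed within the biophysical populations
  expect_true(all(net$syn$target_cell[net$syn$target_pop == "STN"] <=
                    net$sizes$STN))
  expect_true(all(net$syn$target_cell[net$syn$target_pop == "GPe"] <=
                    net$sizes$GPe))
})

test_that("parkinsonian switch changes exactly the listed parameters", {
  ctrl <- micro_network(seed = 5)
  park <- apply_state(micro_network(seed = 5))
  expect_equal(park$condition, "parkinsonian")
  expect_error(apply_state(park), "already applied")

  # rates
  expect_equal(ctrl$rates,
               list(CTX = 10, iMSN = 1.5, STN_surrogate = 14.6,
                    GPe_surrogate = 33.7))
  expect_equal(park$rates,
               list(CTX = 10, iMSN = 6.64, STN_surrogate = 29.5,
                    GPe_surrogate = 14.6))
  # HCN multipliers 0.5 in both classes, nothing else
  expect_equal(park$channel_mult$STN, list(HCN = 0.5))
  expect_equal(park$channel_mult$GPe, list(HCNf = 0.5, HCNs = 0.5))

  # cortical afferent pruning to 70%
  expect_true(all(in_degree(park, "CTX_STN") == round(0.7 * 10)))
  # surviving cortical synapses rescaled by 1/0.7
  key <- function(s) paste(s$target_cell, s$source_cell, s$pset, s$comp)
  cs <- ctrl$syn[startsWith(ctrl$syn$pset, "CTX_STN"), ]
  ps <- park$syn[startsWith(park$syn$pset, "CTX_STN"), ]
  m <- match(key(ps), key(cs))
  expect_false(anyNA(m))
  expect_equal(ps$gbar, cs$gbar[m] / 0.7)

  # field-by-field diff of the remaining synapses
  key_all <- function(s) paste(s$target_pop, s$target_cell, s$source_kind,
                               s$source_cell, s$pset, s$comp)
  keep <- match(key_all(park$syn), key_all(ctrl$syn))
  expect_false(anyNA(keep))
  factors <- park$syn$gbar / ctrl$syn$gbar[keep]
  exp_factor <- c(CTX_STN.AMPA = 1 / 0.7, CTX_STN.NMDA_slow = 1 / 0.7,
                  CTX_STN.NMDA_fast = 1 / 0.7,
                  GPE_STN.GABA_A = 1.5, GPE_STN.GABA_B = 1.5,
                  STN_GPE.AMPA = 1.5, GPE_GPE.GABA_A = 1.5,
                  GPE_GPE.GABA_B = 1.5, iMSN_GPE.GABA_A = 1.5)
  expect_equal(factors, unname(exp_factor[park$syn$pset]), tolerance = 1e-12)
  # GABA-B decay prolonged by 2 ms on the pallido-subthalamic synapse only
  dtau <- park$syn$tau_decay - ctrl$syn$tau_decay[keep]
  expect_true(all(dtau[park$syn$pset == "GPE_STN.GABA_B"] == 2))
  expect_true(all(dtau[park$syn$pset != "GPE_STN.GABA_B"] == 0))
  # release probability raised only on the striato-pallidal synapse
  du <- park$syn$U1 / ctrl$syn$U1[keep]
  expect_true(all(du[park$syn$pset == "iMSN_GPE.GABA_A"] == 1.5))
  expect_true(all(du[park$syn$pset != "iMSN_GPE.GABA_A"] == 1))
  # delays, kinetics, placement untouched
  for (col in c("comp", "delay", "tau_rise", "tau_rec", "tau_facil", "K3",
                "K4", "Kd", "n_hill", "e_rev"))
    expect_equal(park$syn[[col]], ctrl$syn[[col]][keep], label = col)
})

test_that("projection scaling multiplies matching synapses only", {
  net <- micro_network()
  sc <- scale_projection(net, "GPE_STN", 1.5)
  hit <- startsWith(net$syn$pset, "GPE_STN")
  expect_equal(sc$syn$gbar[hit], net$syn$gbar[hit] * 1.5)
  expect_equal(sc$syn$gbar[!hit], net$syn$gbar[!hit])
  expect_error(scale_projection(net, "NOPE", 2), "no synapses")
})

test_that("edge-list export has one row per synapse", {
  net <- micro_network()
  p <- withr::local_tempfile(fileext = ".csv")
  ed <- network_edges(net, p)
  expect_equal(nrow(ed), nrow(net$syn))
  back <- read.csv(p)
  expect_equal(nrow(back), nrow(net$syn))
  expect_true(all(c("source_cell", "target_cell", "receptor", "gbar",
                    "delay") %in% names(back)))
})

test_that("E/I accounting handles the degenerate and linear cases", {
  fake_sim <- function(exc, inh) {
    structure(list(
      dt = 0.025, record_every = 2,
      sizes = list(STN = 10, GPe = 20),
      syn_currents = list(STN = list(cells = 1:3, exc = exc, inh = inh))),
      class = "stngpe_sim")
  }
  ex <- matrix(-1, 100, 3); inh <- matrix(1, 100, 3)
  r <- ei_accounting(fake_sim(ex, inh), "STN")
  expect_equal(r$ei_ratio, 1)
  expect_equal(r$net, 0)
  # zero inhibition reported as +Inf sentinel
  expect_equal(ei_accounting(fake_sim(ex, inh * 0), "STN")$ei_ratio, Inf)
  # doubling excitatory currents doubles the ratio
  expect_equal(ei_accounting(fake_sim(ex * 2, inh), "STN")$ei_ratio, 2)
  # fewer than 3 recorded cells is an error
  broken <- fake_sim(ex[, 1:2], inh[, 1:2])
  broken$syn_currents$STN$cells <- 1:2
  expect_error(ei_accounting(broken, "STN"), ">= 3")
})
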