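test_that("input:output ratio follows the formula on scripted connectomes", {
  # 5 inputs only -> R = +1
  rows <- do.call(rbind, lapply(1:5, function(i) {
    conn_row("OSN_1", "L1", sprintf("c%02d", i), site = c(i * 10, 0, 0))
  }))
  conn <- mini_connectome(rows)
  tab <- io_ratio_table(conn, neurons = "L1")
  expect_equal(tab$ratio, 1)
  expect_equal(tab$n_input, 5)
  # 7 outputs only -> R = -1
  rows <- do.call(rbind, lapply(1:7, function(i) {
    conn_row("L1", "uPN_1", sprintf("c%02d", i), site = c(i * 10, 0, 0))
  }))
  tab <- io_ratio_table(mini_connectome(rows), neurons = "L1")
  expect_equal(tab$ratio, -1)
  # 3 in, 1 out -> R = 0.5
  rows <- rbind(
    do.call(rbind, lapply(1:3, function(i) {
      conn_row("OSN_1", "L1", sprintf("i%d", i), site = c(i * 10, 0, 0))
    })),
    conn_row("L1", "uPN_1", "o1", site = c(500, 0, 0)))
  tab <- io_ratio_table(mini_connectome(rows), neurons = "L1")
  expect_equal(tab$ratio, 0.5)
  # antisymmetry: exchanging the neuron's input and output rows flips R
  flipped <- rbind(
    do.call(rbind, lapply(1:3, function(i) {
      conn_row("L1", "OSN_1", sprintf("i%d", i), site = c(i * 10, 0, 0))
    })),
    conn_row("uPN_1", "L1", "o1", site = c(500, 0, 0)))
  tab2 <- io_ratio_table(mini_connectome(flipped), neurons = "L1")
  expect_equal(tab2$ratio, -0.5)
})

test_that("sites outside every mesh are unassigned and uncounted", {
  rows <- rbind(
    conn_row("OSN_1", "L1", "c1", site = c(0, 0, 0)),
    conn_row("OSN_1", "L1", "c2", site = c(9e3, 9e3, 9e3))) # outside cube
  conn <- mini_connectome(rows)
  assigned <- assign_synapses(conn)
  expect_equal(assigned$post_glomerulus, c("DM2", NA))
  tab <- io_ratio_table(conn, assigned, neurons = "L1")
  expect_equal(tab$n_input, 1)
})

test_that("assignment tallies reproduce the generator's planted ground truth", {
  sim <- tiny_sim(seed = 31)
  assigned <- assign_synapses(sim$connectome)
  tab <- io_ratio_table(sim$connectome, assigned,
                        neurons = sim$ground_truth$patchy)
  gt <- sim$ground_truth$counts
  gt <- gt[grepl("^pLN", gt$neuron_id), ]
  mg <- merge(tab, gt, by = c("neuron_id", "glomerulus"))
  expect_equal(nrow(mg), nrow(gt))
  expect_equal(mg$n_input.x, mg$n_input.y)
  expect_equal(mg$n_output.x, mg$n_output.y)
  expect_equal(mg$ratio.x, mg$ratio.y)
  # sum over glomeruli never exceeds the neuron's total inputs
  for (id in sim$ground_truth$patchy) {
    tot <- sum(sim$connectome$connections$post_neuron == id)
    expect_lte(sum(tab$n_input[tab$neuron_id == id]), tot)
  }
  # pre-site assignment agrees with the analytic generating ellipsoids
  ell <- lapply(sim$connectome$meshes, attr, "ellipsoid")
  probe <- assigned[sample(nrow(assigned), 50), ]
  for (i in seq_len(nrow(probe))) {
    p <- c(probe$post_x[i], probe$post_y[i], probe$post_z[i])
    inside <- names(which(vapply(ell, function(e) {
      sum(((p - e$center) / e$semiaxes)^2) <= 1
    }, logical(1))))
    expect_equal(probe$post_glomerulus[i],
                 if (length(inside)) inside else NA_character_)
  }
})

test_that("partner demographics percentages sum to 100 and match counts", {
  rows <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      conn_row("L2", "L1", sprintf("a%d", i), site = c(i, 0, 0)))),
    do.call(rbind, lapply(1:3, function(i)
      conn_row("uPN_1", "L1", sprintf("b%d", i), site = c(i, 10, 0)))),
    do.call(rbind, lapply(1:3, function(i)
      conn_row("OSN_1", "L1", sprintf("c%d", i), site = c(i, 20, 0)))))
  conn <- mini_connectome(rows)
  dem <- partner_demographics(conn, "L1", "upstream")
  expect_equal(sum(dem$percent), 100)
  expect_equal(dem$percent[dem$category == "LN"], 40)
  expect_equal(dem$percent[dem$category == "uPN"], 30)
  expect_equal(dem$percent[dem$category == "OSN"], 30)
  # single downstream partner: 100% in its category
  rows2 <- conn_row("L1", "uPN_1", "z1", site = c(0, 0, 0))
  dem2 <- partner_demographics(mini_connectome(rows2), "L1", "downstream")
  expect_equal(dem2$percent, 100)
  expect_equal(dem2$category, "uPN")
  # no partners: empty and flagged
  dem3 <- partner_demographics(mini_connectome(rows2), "L1", "upstream")
  expect_equal(nrow(dem3), 0)
  expect_true(isTRUE(attr(dem3, "empty")))
})

test_that("polarity breakdown attributes inputs by home glomerulus and class", {
  # 8 inputs from an excitatory OSN (home DM2), 2 from an inhibitory LN
  rows <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      conn_row("OSN_1", "L1", sprintf("e%d", i), site = c(i, 0, 0)))),
    do.call(rbind, lapply(1:2, function(i)
      conn_row("L2", "L1", sprintf("g%d", i), site = c(i, 50, 0)))))
  conn <- mini_connectome(rows)
  pol <- polarity_breakdown(conn, "L1")
  exc <- pol$percent[pol$class == "excitatory"]
  inh <- pol$percent[pol$class == "inhibitory"]
  expect_equal(exc, 80)
  expect_equal(inh, 20)
  expect_equal(sum(pol$n), 10)
  # home-glomerulus attribution wins for uniglomerular partners even when the
  # synapse site itself lies outside every mesh
  rows2 <- conn_row("OSN_1", "L1", "x1", site = c(9e3, 9e3, 9e3))
  pol2 <- polarity_breakdown(mini_connectome(rows2), "L1")
  expect_equal(pol2$glomerulus[pol2$n > 0], "DM2")
  # planted mixtures from the generator are recovered exactly
  sim <- tiny_sim(seed = 33)
  assigned <- assign_synapses(sim$connectome)
  gt <- sim$ground_truth$polarity
  for (id in sim$ground_truth$patchy[1:2]) {
    pol <- polarity_breakdown(sim$connectome, id, assigned)
    g <- gt[gt$neuron_id == id & gt$n > 0, ]
    mg <- merge(pol, g, by = c("glomerulus", "class"))
    expect_equal(mg$n.x, mg$n.y)
  }
})

test_that("laterality metadata restricts counting to ipsilateral partners", {
  rows <- rbind(
    conn_row("OSN_1", "L1", "c1", site = c(0, 0, 0)),
    conn_row("uPN_1", "L1", "c2", site = c(10, 0, 0)))
  conn <- mini_connectome(rows)
  conn$annotations$side <- ifelse(conn$annotations$neuron_id == "uPN_1",
                                  "right", "left")
  tab <- io_ratio_table(conn, neurons = "L1")
  expect_equal(tab$n_input, 1) # the contralateral uPN row is excluded
})
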