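# Network construction: group table, topographic wiring, random plastic
# initialization, hardware validation, attention lesioning.

test_that("the default architecture instantiates all 23 groups with 766 neurons", {
  net <- cached_untrained_network()
  expect_equal(length(net$groups), 23)
  expect_equal(network_size(net), 766)
  expect_lt(network_size(net), 1000)
  expect_equal(net$groups[["Retina"]]$n, 100)
})

test_that("the shipped group table matches the frozen layer specification", {
  arch <- default_architecture()
  expect_equal(nrow(arch), 23)
  frozen <- list(
    `S1-ver` = c(31, 16, 16, 0), `S1-hor` = c(31, 16, 16, 0),
    `C1-ver-ex` = c(4, 2, 8, 64), `C1-hor-ex` = c(4, 2, 8, 64),
    `C1-ver-inh` = c(4, 2, 32, 0), `C1-hor-inh` = c(4, 2, 32, 0),
    `C1-ver-max` = c(1, 2, 32, 0), `C1-hor-max` = c(16, 2, 32, 0),
    `S2-shape-ex` = c(100, 64, 32, 255), `S2-shape-inh` = c(2, 2, 32, 0),
    `CLA-shape` = c(16, 2, 32, 128),
    `S1-inst` = c(27, 26, 4, 0), `S1-del` = c(27, 26, 4, 0),
    `S2-where-ex` = c(100, 64, 64, 192), `S2-where-inh` = c(16, 2, 32, 0),
    `CLA-where` = c(32, 16, 64, 0), Attention = c(5, 16, 16, 128),
    Target = c(21, 2, 1, 80), Obstacle = c(21, 2, 1, 80),
    `Shape-inh` = c(4, 4, 1, 0), `Shape-decision` = c(13, 3, 1, 0),
    Motor = c(8, 7, 16, 0)
  )
  for (nm in names(frozen)) {
    row <- arch[arch$name == nm, ]
    expect_equal(
      unname(unlist(row[, c("threshold", "leak", "s_plus", "s_minus")])),
      frozen[[nm]],
      info = nm
    )
  }
  sizes <- arch$rows * arch$cols
  expect_equal(sum(sizes), 766)
  # train-only inhibitory layers
  expect_equal(arch$name[arch$train_only], c("S2-shape-inh", "S2-where-inh"))
})

test_that("topographic wiring tiles the source grid into the destination grid", {
  # retina to a motion window layer: 4x4 fields, stride 2, 16 windows
  W <- wire_topographic(c(10, 10), c(4, 4), rf = c(4, 4), stride = c(2, 2))
  expect_equal(dim(W), c(16, 100))
  expect_true(all(rowSums(W) == 16))
  # brute-force window enumeration on a small grid
  W2 <- wire_topographic(c(6, 6), c(3, 3), rf = c(2, 2), stride = c(2, 2))
  expect_equal(dim(W2), c(9, 36))
  expect_true(all(rowSums(W2) == 4))
  src <- matrix(0, 6, 6)
  src[3, 3] <- 1 # falls in the window whose rows/cols are 3:4 x 3:4 = dst (2,2)
  expect_equal(which(propagate(as.numeric(src), W2) > 0), 5)
  # identity case
  expect_equal(wire_topographic(c(3, 4), c(3, 4), c(1, 1), c(1, 1)), diag(12))
  # incompatible tiling is rejected
  expect_error(wire_topographic(c(10, 10), c(4, 4), c(3, 3), c(2, 2)), "tiles")
})

test_that("random plastic wiring is uniform on [0,1) and seed-reproducible", {
  set.seed(77)
  W1 <- wire_random(100, 100)
  set.seed(77)
  W2 <- wire_random(100, 100)
  expect_identical(W1, W2)
  expect_true(all(W1 >= 0 & W1 < 1))
  expect_equal(mean(W1), 0.5, tolerance = 0.02 / 0.5)
})

test_that("identical seeds give identical networks, different seeds differ", {
  a <- build_network(seed = 101)
  b <- build_network(seed = 101)
  c <- build_network(seed = 102)
  expect_identical(
    a$conns[["S2-shape-ex->CLA-shape"]]$W,
    b$conns[["S2-shape-ex->CLA-shape"]]$W
  )
  expect_false(identical(
    a$conns[["S2-shape-ex->CLA-shape"]]$W,
    c$conns[["S2-shape-ex->CLA-shape"]]$W
  ))
})

test_that("hardware validation passes on defaults and flags violations", {
  net <- cached_untrained_network()
  rep <- validate_hardware(net)
  param_checks <- rep[rep$scope == "group", ]
  expect_true(all(param_checks$pass))
  # pre-binarization: plastic connections fail the binarity check
  bin_checks <- rep[rep$check == "binary_synapses", ]
  plastic <- vapply(net$conns, function(cn) cn$plastic, logical(1))
  expect_equal(sum(!bin_checks$pass), sum(plastic))
  # a consolidated network passes everything
  trained <- cached_standard_network()
  expect_true(all(validate_hardware(trained)$pass))
  # an out-of-range threshold is reported
  bad <- clone_network(net)
  bad$groups[["Motor"]]$threshold <- 300
  bad_rep <- validate_hardware(bad)
  expect_false(bad_rep$pass[bad_rep$item == "Motor" &
    bad_rep$check == "threshold_range"])
})

test_that("attention outgoing connections are inhibitory everywhere", {
  net <- cached_untrained_network()
  for (cn in net$conns) {
    if (cn$source == "Attention") expect_equal(cn$sign, "inhibitory")
  }
})

test_that("severing attention zeroes all its outputs, idempotently, without
           touching the source network", {
  net <- cached_untrained_network()
  before <- lapply(net$conns, function(cn) sum(cn$W))
  cut1 <- sever_attention(net)
  for (nm in names(cut1$conns)) {
    if (cut1$conns[[nm]]$source == "Attention") {
      expect_equal(sum(cut1$conns[[nm]]$W), 0)
    } else {
      expect_equal(sum(cut1$conns[[nm]]$W), before[[nm]])
    }
  }
  cut2 <- sever_attention(cut1)
  expect_equal(
    lapply(cut2$conns, function(cn) sum(cn$W)),
    lapply(cut1$conns, function(cn) sum(cn$W))
  )
  # original untouched
  expect_equal(lapply(net$conns, function(cn) sum(cn$W)), before)
})

test_that("classifier pools partition their layers", {
  net <- cached_untrained_network()
  shape_pools <- net$pools[["CLA-shape"]]
  expect_equal(names(shape_pools), c("T", "L", "J"))
  expect_equal(sort(unname(unlist(shape_pools))), 1:30)
  where_pools <- net$pools[["CLA-where"]]
  expect_equal(length(where_pools), 8)
  expect_true(all(lengths(where_pools) == 10))
  expect_equal(sort(unname(unlist(where_pools))), 1:80)
})
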