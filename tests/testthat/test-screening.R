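test_that("library enumeration is the deduplicated Cartesian product", {
  lib1 <- enumerate_library("c1ccccc1[R1]", list(R1 = c("O", "N", "Cl")))
  expect_equal(nrow(lib1), 3)
  expect_equal(lib1$smiles, c("c1ccccc1O", "c1ccccc1N", "c1ccccc1Cl"))

  lib2 <- enumerate_library("c1cc([R1])ccc1[R2]",
                            list(R1 = c("O", "N", "S"), R2 = c("C", "F")))
  expect_equal(nrow(lib2), 6)

  # duplicates collapse; count checked against brute-force set construction
  subs <- list(R1 = c("O", "O", "N"), R2 = c("C", "F"))
  lib3 <- enumerate_library("c1cc([R1])ccc1[R2]", subs)
  oracle <- unique(as.vector(outer(
    subs$R1, subs$R2,
    function(a, b) {
      mapply(function(x, y) {
        sub("[R2]", y, sub("[R1]", x, "c1cc([R1])ccc1[R2]", fixed = TRUE),
            fixed = TRUE)
      }, a, b)
    }
  )))
  expect_setequal(lib3$smiles, oracle)
  expect_equal(nrow(lib3), 4)

  # deterministic order and ids
  expect_identical(lib2$candidate_id, sprintf("NEW%02d", 1:6))
  expect_identical(enumerate_library("c1cc([R1])ccc1[R2]",
                                     list(R1 = c("O", "N", "S"),
                                          R2 = c("C", "F")))$smiles,
                   lib2$smiles)

  expect_error(enumerate_library("c1ccccc1[R1]", list(R2 = "O")), "R2")
  expect_error(enumerate_library("c1ccccc1[R1][R9]", list(R1 = "O")), "R9")
  expect_error(enumerate_library("c1ccccc1[R1]", list(R1 = character(0))),
               "no substituents")
})

test_that("candidate prediction matches direct evaluation and gates on leverage", {
  bank <- published_models()
  all_desc <- unique(unlist(lapply(bank, function(m) names(m$coefficients))))

  # zero-vector candidate: six predictions equal the six printed intercepts
  zero <- tibble::as_tibble(as.list(setNames(rep(0, length(all_desc)), all_desc)))
  zero$compound_id <- "zero"
  scr <- predict_candidates(zero, bank)
  expect_identical(
    unname(vapply(names(bank), function(k) scr[[paste0("pred_", k)]],
                  numeric(1))),
    unname(vapply(bank, function(m) m$intercept, numeric(1)))
  )

  # 50 random candidates: predictions equal the linear forms exactly
  set.seed(181)
  cands <- tibble::as_tibble(matrix(rnorm(50 * length(all_desc)), 50,
                                    dimnames = list(NULL, all_desc)))
  cands$compound_id <- sprintf("c%02d", 1:50)
  scr <- predict_candidates(cands, bank)
  for (k in names(bank)) {
    m <- bank[[k]]
    oracle <- m$intercept +
      as.matrix(cands[, names(m$coefficients)]) %*% m$coefficients
    expect_equal(scr[[paste0("pred_", k)]], drop(oracle), tolerance = 1e-12)
  }

  # with training data supplied, centroid candidates pass every gate
  train <- make_published_dataset("Cd_logB", n = 50, sigma = 0.3, seed = 182)
  centroid <- tibble::as_tibble(lapply(
    train$data[names(bank$Cd_logB$coefficients)], mean
  ))
  centroid$compound_id <- "centroid"
  scr2 <- predict_candidates(centroid, bank["Cd_logB"],
                             train_data = list(Cd_logB = train$data))
  expect_true(scr2$in_ad_Cd_logB)

  expect_error(predict_candidates(tibble::tibble(RBN = 1), bank), "missing")
})

test_that("Pareto front equals the independent staircase oracle", {
  # trivial dominance
  pts <- rbind(c(2, 2), c(1, 1))
  expect_identical(pareto_front(pts), c(TRUE, FALSE))
  # all-identical points are all on the front
  same <- matrix(1, 5, 2)
  expect_true(all(pareto_front(same)))
  # 100 random 2-D points vs the sweep oracle
  set.seed(191)
  pts <- matrix(rnorm(200), 100, 2)
  expect_identical(pareto_front(pts), pareto_staircase_oracle(pts))
  # with ties
  pts_t <- rbind(pts, pts[1:10, ])
  expect_identical(pareto_front(pts_t), pareto_staircase_oracle(pts_t))
  # adding a dominated candidate never changes the front membership
  worst <- matrix(apply(pts, 2, min) - 1, 1)
  expect_identical(pareto_front(rbind(pts, worst))[1:100], pareto_front(pts))
})

test_that("consensus selection crosses metals and respects AD gates", {
  bank <- published_models()
  all_desc <- unique(unlist(lapply(bank, function(m) names(m$coefficients))))
  set.seed(201)
  cands <- tibble::as_tibble(matrix(rnorm(40 * length(all_desc), sd = 0.8), 40,
                                    dimnames = list(NULL, all_desc)))
  cands$compound_id <- sprintf("c%02d", 1:40)
  scr <- predict_candidates(cands, bank)
  sel <- pareto_select(scr)
  expect_setequal(names(sel), c("compound_id", "pareto_rank_Cd",
                                "pareto_rank_Cu", "pareto_rank_Pb",
                                "ideal_distance", "consensus"))
  # consensus candidates are rank 1 for every metal
  cons <- sel[sel$consensus, ]
  if (nrow(cons) > 0) {
    expect_true(all(cons$pareto_rank_Cd == 1 & cons$pareto_rank_Cu == 1 &
                      cons$pareto_rank_Pb == 1))
  }
  # rank-1 sets match a direct dominance scan per metal (logB max, PS min)
  for (met in c("Cd", "Cu", "Pb")) {
    obj <- cbind(scr[[paste0("pred_", met, "_logB")]],
                 -scr[[paste0("pred_", met, "_PS")]])
    expect_identical(sel[[paste0("pareto_rank_", met)]][
      match(scr$compound_id, sel$compound_id)] == 1L,
      pareto_front(obj))
  }

  # candidates failing an AD gate are excluded from ranking
  train <- lapply(names(bank), function(k) {
    make_published_dataset(k, n = 50, sigma = 0.3,
                           seed = 300 + match(k, names(bank)))$data
  })
  names(train) <- names(bank)
  far <- cands
  far[1, all_desc] <- 25  # far outside every training cloud
  scr2 <- predict_candidates(far, bank, train_data = train)
  sel2 <- pareto_select(scr2)
  expect_true(is.na(sel2$pareto_rank_Cd[sel2$compound_id == "c01"]))
  expect_false(sel2$consensus[sel2$compound_id == "c01"])

  # maximize-PS direction flips the PS objective
  sel_max <- pareto_select(scr, ps_direction = "max")
  obj_max <- cbind(scr$pred_Cd_logB, scr$pred_Cd_PS)
  expect_identical(sel_max$pareto_rank_Cd[
    match(scr$compound_id, sel_max$compound_id)] == 1L,
    pareto_front(obj_max))
})
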