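# Stage 2: greedy depth-limited CART on CATE estimates, subgroup
# intervals, rendering.

test_that("a constant response yields a root-only tree", {
  x <- data.frame(a = runif(30), b = runif(30))
  tr <- fit_cart(x, rep(2.5, 30), max_depth = 3, min_leaf = 2, cp = 0)
  expect_equal(nrow(tr), 1)
  expect_true(tr$is_leaf[1])
  expect_equal(tr$estimate[1], 2.5)
  expect_equal(tr$prop[1], 1)
})

test_that("a perfectly separable binary signal is found exactly", {
  set.seed(41)
  diabetes <- rbinom(120, 1, 0.4)
  x <- data.frame(age = runif(120, 40, 80), diabetes = diabetes)
  t_val <- ifelse(diabetes == 1, 2, 6)
  tr <- fit_cart(x, t_val, max_depth = 3, min_leaf = 5, cp = 0.01)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$var[1], "diabetes")
  leaves <- tr[tr$is_leaf, ]
  expect_setequal(leaves$estimate, c(2, 6))
  expect_equal(leaves$prop[leaves$estimate == 2], mean(diabetes == 1))
})

test_that("the greedy first split matches exhaustive enumeration", {
  for (seed in 1:25) {
    case <- random_cart_case(seed)
    oracle <- brute_force_first_split(case$x, case$y, min_leaf = 1)
    tr <- fit_cart(case$x, case$y, max_depth = 1, min_leaf = 1, cp = 0)
    if (is.null(oracle) || oracle$reduction <= 0) {
      expect_true(tr$is_leaf[1])
    } else {
      expect_equal(tr$var[1], oracle$var)
      if (!is.na(oracle$cut)) expect_equal(tr$cut[1], oracle$cut)
      else expect_setequal(tr$levels_left[[1]], oracle$levels_left)
    }
  }
})

test_that("the first split agrees with rpart on random data", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 80
    x <- data.frame(u = round(runif(n), 2), v = round(runif(n), 2))
    y <- 2 * (x$u > 0.5) + rnorm(n)
    tr <- fit_cart(x, y, max_depth = 1, min_leaf = 10, cp = 0.01)
    rp <- rpart::rpart(y ~ ., data = cbind(x, y = y),
                       control = rpart::rpart.control(
                         maxdepth = 1, minbucket = 10, minsplit = 20,
                         cp = 0.01, xval = 0))
    if (is.null(rp$splits)) {
      expect_true(tr$is_leaf[1])
    } else {
      expect_false(tr$is_leaf[1])
      expect_equal(tr$var[1], rownames(rp$splits)[1])
      # same partition of the rows
      left <- x[[tr$var[1]]] <= tr$cut[1]
      rp_left <- x[[rownames(rp$splits)[1]]] < rp$splits[1, "index"]
      expect_true(identical(left, rp_left) || identical(left, !rp_left))
    }
  }
})

test_that("trees conserve proportions, means, depth and leaf sizes", {
  for (seed in 1:8) {
    set.seed(seed + 200)
    n <- 300
    x <- data.frame(age = runif(n, 40, 80), weight = runif(n, 50, 120),
                    resp = factor(sample(c("open", "niv", "imv"), n, TRUE)))
    y <- 3 * (x$age > 60) - 2 * (x$resp == "imv") + rnorm(n)
    md <- sample(1:3, 1)
    ml <- sample(c(10, 20), 1)
    tr <- fit_cart(x, y, max_depth = md, min_leaf = ml, cp = 0.005)
    leaves <- tr[tr$is_leaf, ]
    expect_equal(sum(leaves$prop), 1, tolerance = 1e-9)
    expect_equal(sum(leaves$prop * leaves$estimate) / sum(leaves$prop),
                 tr$estimate[1], tolerance = 1e-9)
    expect_lte(max(tr$depth), md)
    expect_gte(min(leaves$n), ml)
    for (k in which(!tr$is_leaf)) {
      expect_equal(tr$prop[tr$child_left[k]] + tr$prop[tr$child_right[k]],
                   tr$prop[k], tolerance = 1e-12)
    }
  }
})

test_that("tiny samples give a root-only tree rather than an error", {
  x <- data.frame(a = runif(10))
  tr <- fit_cart(x, rnorm(10), max_depth = 3, min_leaf = 20, cp = 0.01)
  expect_equal(nrow(tr), 1)
})

test_that("exact ties break toward the lower variable index", {
  x <- data.frame(first = c(0, 0, 1, 1), second = c(0, 0, 1, 1))
  tr <- fit_cart(x, c(1, 1, 5, 5), max_depth = 1, min_leaf = 1, cp = 0)
  expect_equal(tr$var[1], "first")
})

test_that("subgroup intervals aggregate member draws within each draw", {
  cate <- local({
    ds <- standardize_covariates(tiny_trial(300, seed = 42))
    estimate_cate(ds, "dawols", test_config(43))
  })
  tree <- fit_subgroups(cate, max_depth = 2, min_leaf = 30, cp = 0.005)
  draws <- bartcate:::cate_draws(cate)

  # whole-sample node: interval equals the overall-mean interval
  overall <- rowMeans(draws)
  expect_equal(tree$conf.low[1], unname(quantile(overall, 0.025)))
  expect_equal(tree$conf.high[1], unname(quantile(overall, 0.975)))

  leaves <- tree[tree$is_leaf, ]
  expect_equal(sum(leaves$prop * leaves$estimate), tree$estimate[1],
               tolerance = 1e-9)

  bad <- tree
  bad$members[[1]] <- c("nobody", bad$members[[1]][-1])
  expect_error(attach_subgroup_intervals(bad, cate), "ids do not match")
})

test_that("cutpoints of fit_subgroups read in original units", {
  set.seed(44)
  ds <- standardize_covariates(tiny_trial(400, seed = 44))
  cate <- estimate_cate(ds, "dawols", test_config(45))
  tree <- fit_subgroups(cate, max_depth = 3, min_leaf = 20, cp = 0.0005)
  agecuts <- tree$cut[!tree$is_leaf & tree$var == "age"]
  wcuts <- tree$cut[!tree$is_leaf & tree$var == "weight"]
  expect_true(all(agecuts > 18 & agecuts < 100))
  expect_true(all(wcuts > 35 & wcuts < 250))
})

test_that("render and parse round-trip the tree document", {
  set.seed(45)
  x <- data.frame(age = runif(200, 40, 80),
                  resp = factor(sample(c("open", "niv", "imv"), 200, TRUE),
                                levels = c("open", "niv", "imv")))
  y <- 2 * (x$age > 60) + (x$resp == "imv") + rnorm(200, 0, 0.3)
  tr <- fit_cart(x, y, max_depth = 2, min_leaf = 20, cp = 0.01)

  txt <- render_tree(tr, "text")
  expect_match(txt, "all: ")
  expect_match(txt, "prop 1.000")

  back <- parse_subgroup_tree(render_tree(tr, "json"))
  for (col in c("node", "parent", "depth", "var", "cut", "is_leaf", "n",
                "estimate")) {
    expect_equal(back[[col]], tr[[col]], tolerance = 1e-12)
  }
  expect_equal(back$levels_left, tr$levels_left)
  expect_equal(round(back$prop, 12), round(tr$prop, 12))

  dot <- render_tree(tr, "dot")
  expect_match(dot, "digraph")
  expect_match(dot, "->")

  root_only <- fit_cart(x["age"], rep(1, 200), max_depth = 0)
  expect_match(render_tree(root_only, "text"), "prop 1.000")
})
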