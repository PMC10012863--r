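test_that("a root node with a uniform CPT has a uniform prior marginal", {
  schema <- tibble::tibble(variable = "coin", category = "treatment_planning",
                           states = list(c("heads", "tails")),
                           applicable = list("all"))
  net <- rt_network(tibble::tibble(from = character(0), to = character(0)),
                    list(coin = list(parents = character(0),
                                     prob = matrix(c(.5, .5), 1))),
                    schema)
  expect_equal(unname(marginal(net, "coin")), c(.5, .5))
})

two_node_net <- function(p_a = c(.3, .7), p_b_given = rbind(c(.9, .1), c(.2, .8))) {
  schema <- tibble::tibble(
    variable = c("a", "b"),
    category = "treatment_planning",
    states = list(c("a1", "a2"), c("b1", "b2")),
    applicable = list("all", "all"))
  rt_network(tibble::tibble(from = "a", to = "b"),
             list(a = list(parents = character(0), prob = matrix(p_a, 1)),
                  b = list(parents = "a", prob = p_b_given)),
             schema)
}

test_that("evidence on all parents returns the CPT row exactly", {
  net <- two_node_net()
  expect_equal(unname(marginal(net, "b", c(a = "a1"))), c(.9, .1))
  expect_equal(unname(marginal(net, "b", c(a = "a2"))), c(.2, .8))
})

test_that("joint_probability is the product of the selected CPT entries", {
  # two independent uniform binary nodes
  schema <- tibble::tibble(variable = c("x", "y"), category = "treatment_planning",
                           states = list(c("x1", "x2"), c("y1", "y2")),
                           applicable = list("all", "all"))
  net <- rt_network(tibble::tibble(from = character(0), to = character(0)),
                    list(x = list(parents = character(0), prob = matrix(c(.5, .5), 1)),
                         y = list(parents = character(0), prob = matrix(c(.5, .5), 1))),
                    schema)
  expect_equal(joint_probability(net, c(x = "x1", y = "y2")), 0.25)

  # degenerate chain: P(a1) = 1, P(b1 | a1) = 1
  chain <- two_node_net(p_a = c(1, 0), p_b_given = rbind(c(1, 0), c(.5, .5)))
  expect_equal(joint_probability(chain, c(a = "a1", b = "b1")), 1)
  expect_error(joint_probability(chain, c(a = "a1")),
               class = "planreviewr_bn_error")

  # 4-node random network against full-joint enumeration
  net4 <- rand_small_network(42, n_nodes = 4)
  j <- enum_joint(net4)
  for (k in c(1, 5, nrow(j))) {
    asg <- vapply(net4$nodes, function(v) j[[v]][k], character(1))
    expect_equal(joint_probability(net4, asg), j$prob[k], tolerance = 1e-12)
  }
})

test_that("variable elimination matches joint enumeration on random small networks", {
  for (s in 1:25) {
    net <- rand_small_network(s)
    withr::with_seed(1000 + s, {
      n_ev <- sample(0:(length(net$nodes) - 1), 1)
      ev_vars <- sample(setdiff(net$nodes, net$nodes[1]), n_ev)
      evidence <- vapply(ev_vars, function(v) sample(net$states[[v]], 1),
                         character(1))
      names(evidence) <- ev_vars
      target <- net$nodes[1]
    })
    got <- tryCatch(unname(marginal(net, target, evidence)),
                    planreviewr_impossible_evidence = function(e) NULL)
    want <- enum_marginal(net, target, evidence)
    if (is.null(got)) {
      expect_true(all(!is.finite(want)) || sum(want, na.rm = TRUE) == 0)
    } else {
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("zero-probability evidence raises an explicit impossible-evidence condition", {
  net <- two_node_net(p_a = c(1, 0), p_b_given = rbind(c(1, 0), c(.5, .5)))
  expect_error(marginal(net, "a", c(b = "b2")),
               class = "planreviewr_impossible_evidence")
  expect_equal(evidence_probability(net, c(b = "b2")), 0)
})

test_that("targets cannot simultaneously be evidence", {
  net <- two_node_net()
  expect_error(marginal(net, "b", c(b = "b1", a = "a1")),
               class = "planreviewr_bn_error")
})
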