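test_that("movement: healthy agents follow commands, damaged agents invert them", {
  w <- grid_world()
  a <- agent_state("x", c(3, 3), w)
  expect_equal(step_agent(w, a, "right")$agent$cell, c(3L + 1L, 3L))
  expect_equal(step_agent(w, a, "up")$agent$cell, c(3L, 2L))
  a$damaged <- TRUE
  expect_equal(step_agent(w, a, "right")$agent$cell, c(2L, 3L))
  expect_equal(step_agent(w, a, "up")$agent$cell, c(3L, 4L))
  # blocked moves leave the agent in place
  edge <- agent_state("x", c(1, 1), w)
  expect_equal(step_agent(w, edge, "left")$agent$cell, c(1L, 1L))
  near_wall <- agent_state("x", c(w$wall_col - 1, 2), w)
  expect_equal(step_agent(w, near_wall, "right")$agent$cell,
               c(w$wall_col - 1L, 2L))
})

test_that("collision, switch, and recovery events fire and update state", {
  w <- grid_world()
  a <- agent_state("x", w$danger_cell + c(1, 0), w)
  hit <- step_agent(w, a, "left")
  expect_true("collision" %in% hit$events)
  expect_true(hit$agent$damaged)

  sw <- agent_state("x", w$switch_cell + c(0, 1), w)
  opened <- step_agent(w, sw, "up")
  expect_true("switch" %in% opened$events)
  expect_true(opened$world$passage_open)

  # a damaged agent crossing into the safety zone recovers immediately
  w2 <- w; w2$passage_open <- TRUE
  dmg <- agent_state("x", c(w$wall_col, 4), w2)
  dmg$damaged <- TRUE
  # damaged movement inverts: command left moves right into safety
  rec <- step_agent(w2, dmg, "left")
  expect_true("recovery" %in% rec$events)
  expect_false(rec$agent$damaged)
  expect_equal(rec$agent$color, "green")
  expect_equal(rec$agent$zone, "safety")
})

test_that("with the passage closed no step sequence crosses between zones", {
  w <- grid_world()
  # exhaustive reachability from a danger-zone cell over closed-world moves
  dist <- empathysim:::bfs_distances(w, c(2, 2))
  safety <- which(matrix(seq_len(w$width) > w$wall_col, w$width, w$height),
                  arr.ind = TRUE)
  expect_true(all(!is.finite(dist[safety])))
  # opening the passage creates exactly one crossing column
  w$passage_open <- TRUE
  dist2 <- empathysim:::bfs_distances(w, c(2, 2))
  expect_true(all(is.finite(dist2[safety])))
})

test_that("package BFS distances agree with an independent graph library", {
  skip_if_not_installed("igraph")
  w <- grid_world()
  w$passage_open <- TRUE
  cells <- expand.grid(col = seq_len(w$width), row = seq_len(w$height))
  free <- cells[!apply(cells, 1, function(c2) empathysim:::cell_blocked(w, c2)), ]
  id <- function(c2) paste(c2[1], c2[2], sep = ",")
  edges <- character()
  for (i in seq_len(nrow(free))) {
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- as.integer(free[i, ]) + d
      if (!empathysim:::cell_blocked(w, nb))
        edges <- c(edges, id(as.integer(free[i, ])), id(nb))
    }
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  from <- c(2, 2)
  d_ig <- igraph::distances(g, v = id(from))
  d_pkg <- empathysim:::bfs_distances(w, from)
  for (i in seq_len(nrow(free))) {
    cell <- as.integer(free[i, ])
    expect_equal(unname(d_pkg[cell[1], cell[2]]),
                 unname(d_ig[1, id(cell)]))
  }
})

test_that("self-sensing scores the prediction error of the actual move", {
  w <- grid_world()
  a <- agent_state("x", c(3, 3), w)
  res <- step_agent(w, a, "right")
  s <- sense_self(w, a, "right", res$agent)
  expect_equal(s$report$fe_raw, 0)
  expect_false(s$report$pain)
  expect_equal(s$agent$color, "green")

  # damaged inverted move: predicted one cell right, actual one cell left
  a$damaged <- TRUE
  res <- step_agent(w, a, "right")
  s <- sense_self(w, a, "right", res$agent)
  expect_equal(s$report$fe_raw, 12500)
  expect_equal(s$report$fe_clipped, 3125)
  expect_true(s$report$pain)
  expect_equal(s$agent$color, "red")

  # damaged inverted move into a wall: predicted move, actual stay
  b <- agent_state("x", c(2, 3), w)
  b$damaged <- TRUE
  res <- step_agent(w, b, "right")  # inverted left is blocked at column 1
  expect_equal(res$agent$cell, c(1L, 3L))
  b2 <- agent_state("x", c(1, 3), w)
  b2$damaged <- TRUE
  res2 <- step_agent(w, b2, "right")  # inverted left: out of bounds, stays
  s2 <- sense_self(w, b2, "right", res2$agent)
  expect_equal(s2$report$fe_raw, 3125)
  expect_true(s2$report$pain)
})

test_that("pose stays consistent with the cell after every step", {
  w <- grid_world()
  a <- agent_state("x", c(4, 4), w)
  set.seed(3)
  for (i in 1:40) {
    a <- step_agent(w, a, random_walk_policy())$agent
    expect_equal(a$pose$vertices,
                 pose_from_cell(a$cell, w$cell_length)$vertices)
    expect_equal(a$zone, empathysim:::cell_zone(w, a$cell))
  }
})

test_that("percepts mirror the target's color, for self and other alike", {
  w <- grid_world()
  a <- agent_state("a", c(3, 3), w)
  b <- agent_state("b", c(8, 3), w)
  expect_equal(perceive_other(a, b), "perceive-green")
  b$color <- "red"
  expect_equal(perceive_other(a, b), "perceive-red")
  expect_equal(perceive_other(b, b), "perceive-red")  # self-perception
})

test_that("the random-walk policy is uniform and reproducible", {
  set.seed(11)
  draws <- replicate(10000, random_walk_policy())
  freq <- table(draws) / length(draws)
  expect_true(all(abs(freq - 0.25) < 0.02))
  set.seed(5); a <- replicate(20, random_walk_policy())
  set.seed(5); b <- replicate(20, random_walk_policy())
  expect_identical(a, b)
})
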