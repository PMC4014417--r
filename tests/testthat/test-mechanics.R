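# Force terms of the node-and-spring cell model, checked against closed-form
# arithmetic, symmetry requirements and a finite-difference energy oracle.

test_that("joint forces obey Hooke's law and action-reaction", {
  p <- mech_params()
  cl <- make_cell(p)
  f0 <- joint_forces(cl, p)
  expect_equal(max(abs(f0)), 0)  # rest configuration, zero displacement

  # displace node 2 by 0.01 um along +x: its two joints each stretch 0.01
  cl2 <- cl
  cl2$nodes[2, 1] <- cl2$nodes[2, 1] + 0.01
  f <- joint_forces(cl2, p)
  expect_equal(f[2, 1], -2 * p$k_joint * 0.01, tolerance = 1e-12)
  expect_equal(sum(f[, 1]), 0, tolerance = 1e-9 * p$k_joint * 0.01)

  cl3 <- bent_cell(p)
  f3 <- joint_forces(cl3, p)
  expect_lt(max(abs(force_sum(f3))), 1e-9 * max(1, max(abs(f3))))

  cl_bad <- cl
  cl_bad$nodes[1, 1] <- NaN
  expect_error(joint_forces(cl_bad, p), "non-finite")
})

test_that("bending forces vanish when straight, cancel per triple, and match
           the finite-difference energy gradient", {
  p <- mech_params()
  cl <- make_cell(p)
  expect_equal(max(abs(bending_forces(cl, p))), 0)  # collinear: theta = pi

  clb <- bent_cell(p, amplitude = 0.15)
  f <- bending_forces(clb, p)
  # forces live on nodes only and sum to zero (per-triple cancellation)
  expect_lt(max(abs(force_sum(f))), 1e-9 * max(abs(f)))

  # oracle: central finite differences of the bending energy
  h <- 1e-6
  for (i in seq_len(p$n_nodes)) {
    for (d in 1:2) {
      up <- clb; up$nodes[i, d] <- up$nodes[i, d] + h
      dn <- clb; dn$nodes[i, d] <- dn$nodes[i, d] - h
      fd <- -(bending_energy(up, p) - bending_energy(dn, p)) / (2 * h)
      expect_equal(f[i, d], fd, tolerance = 1e-5)
    }
  }

  cl_deg <- clb
  cl_deg$nodes[2, ] <- cl_deg$nodes[3, ]
  expect_error(bending_forces(cl_deg, p), "degenerate")
})

test_that("propulsion acts on interior nodes toward the leading pole", {
  p <- mech_params()
  cl <- make_cell(p)  # straight along +x
  f <- propulsion_forces(cl, p)
  expect_equal(f[1, ], c(0, 0))
  expect_equal(f[p$n_nodes, ], c(0, 0))
  for (i in 2:(p$n_nodes - 1)) expect_equal(f[i, ], c(p$f_prop, 0))

  p3 <- mech_params(n_nodes = 3, cell_length = 2.5, cell_width = 0.5)
  f3 <- propulsion_forces(make_cell(p3), p3)
  expect_equal(sum(rowSums(abs(f3)) > 0), 1)  # exactly one propelled node

  # bent cell: each interior force is tangent to its leading segment
  clb <- bent_cell(p, amplitude = 0.3)
  fb <- propulsion_forces(clb, p)
  for (i in 2:(p$n_nodes - 1)) {
    seg <- clb$nodes[i - 1, ] - clb$nodes[i, ]
    seg <- seg / sqrt(sum(seg^2))
    expect_equal(fb[i, ], p$f_prop * seg, tolerance = 1e-12)
  }
})

test_that("drag is linear in velocity and antiparallel to it", {
  p <- mech_params()
  cl <- make_cell(p, speed = 0)
  expect_equal(max(abs(drag_forces(cl, p))), 0)

  cl$node_vel[3, ] <- c(4, 0)
  f <- drag_forces(cl, p)
  expect_equal(f[3, ], c(-p$gamma_node * 4, 0))

  set.seed(7)
  cl$node_vel <- matrix(rnorm(2 * p$n_nodes), ncol = 2)
  f <- drag_forces(cl, p)
  dots <- rowSums(f[seq_len(p$n_nodes), ] * cl$node_vel)
  expect_true(all(dots <= 0))
})

test_that("drag calibration balances total propulsion at the target speed", {
  p <- mech_params()
  total_prop <- (p$n_nodes - 2) * p$f_prop
  expect_equal(total_prop, 60)  # 5 interior nodes x 12 pN
  expect_equal(p$gamma_node * n_bodies(p) * p$target_speed, total_prop,
               tolerance = 1e-12)

  p2 <- mech_params(f_prop = 24)
  expect_equal(p2$gamma_node, 2 * p$gamma_node, tolerance = 1e-12)

  p_bad <- unclass(p)
  p_bad$f_prop <- -1
  expect_error(calibrate_drag(p_bad), "positive")
})

test_that("adhesion forces load only the lateral displacement and handle
           break/reform", {
  p <- mech_params()
  ap <- adhesion_params(n_nodes = p$n_nodes)
  cl <- make_cell(p)
  bonds <- init_bonds(cl, ap)

  res <- adhesion_forces(cl, bonds, ap, p, now = 0)
  expect_equal(max(abs(res$forces)), 0)  # at anchor
  expect_true(all(res$bonds$intact))

  # pure axial slide: free (anchor follows along the bond line)
  cl_ax <- cl
  cl_ax$nodes[, 1] <- cl_ax$nodes[, 1] + 0.5
  res <- adhesion_forces(cl_ax, bonds, ap, p, now = 0)
  expect_equal(max(abs(res$forces)), 0)

  # lateral offset of 0.01 um at node 3: Hooke restoring force
  cl_lat <- cl
  cl_lat$nodes[3, 2] <- cl_lat$nodes[3, 2] + 0.01
  res <- adhesion_forces(cl_lat, bonds, ap, p, now = 0)
  expect_equal(res$forces[3, 2], -ap$kappa * 0.01, tolerance = 1e-6)

  # beyond d_break: bond breaks, zero force, reform scheduled in the future
  set.seed(1)
  cl_far <- cl
  cl_far$nodes[3, 2] <- cl_far$nodes[3, 2] + 2 * ap$d_break
  res <- adhesion_forces(cl_far, bonds, ap, p, now = 5)
  k <- which(res$bonds$node == 3)
  expect_false(res$bonds$intact[k])
  expect_gt(res$bonds$reform_at[k], 5)
  expect_equal(max(abs(res$forces[3, ])), 0)

  # a broken bond past its reform time re-anchors at the current position
  res2 <- adhesion_forces(cl_far, res$bonds, ap, p,
                          now = res$bonds$reform_at[k] + 1e-9)
  expect_true(res2$bonds$intact[k])
  expect_equal(res2$bonds$ax[k], cl_far$nodes[3, 1])

  expect_error(
    adhesion_forces(cl, bonds, adhesion_params(mode = "VCM"), p),
    "VCM"
  )
})

test_that("kappa = 0 adhesion is identically zero force", {
  p <- mech_params()
  ap <- adhesion_params(kappa = 0, n_nodes = p$n_nodes)
  clb <- bent_cell(p, amplitude = 0.2)
  bonds <- init_bonds(make_cell(p), ap)
  res <- adhesion_forces(clb, bonds, ap, p, now = 0)
  expect_identical(max(abs(res$forces)), 0)
})

test_that("contact detection finds circle overlaps with correct depth and
           normal, and nothing for separated cells", {
  p <- mech_params()
  c1 <- make_cell(p, head = c(0, 0))
  c2 <- make_cell(p, head = c(0, 2 * p$cell_width))
  w <- make_world(list(c1, c2), p)
  expect_equal(nrow(detect_contacts(w)), 0)

  # two circles at centre distance 1.9 r: depth 0.1 r, normal along centres
  r <- p$node_radius
  c3 <- make_cell(p, head = c(20, 0))
  c4 <- make_cell(p, head = c(20 - p$cell_length - 1.9 * r + 2 * r, 0))
  # c4's leading node sits 1.9 r behind c3's lagging node along x
  w2 <- make_world(list(c3, c4), p)
  ev <- detect_contacts(w2)
  ev <- ev[ev$body_a <= p$n_nodes & ev$body_b <= p$n_nodes, ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$depth, 0.1 * r, tolerance = 1e-9)
  expect_equal(abs(ev$nx), 1, tolerance = 1e-12)

  # randomized placements: circle-circle events agree with an independent
  # all-pairs distance check
  set.seed(11)
  for (rep in 1:5) {
    ca <- make_cell(p, head = runif(2, -2, 2), angle_deg = runif(1, 0, 360))
    cb <- make_cell(p, head = runif(2, -2, 2), angle_deg = runif(1, 0, 360))
    wr <- make_world(list(ca, cb), p)
    ev <- detect_contacts(wr)
    ev_cc <- ev[ev$body_a <= p$n_nodes & ev$body_b <= p$n_nodes, ]
    dmat <- as.matrix(dist(rbind(ca$nodes, cb$nodes)))
    nn <- p$n_nodes
    brute <- sum(dmat[seq_len(nn), nn + seq_len(nn)] < 2 * p$node_radius)
    expect_equal(nrow(ev_cc), brute)
  }
})

test_that("contact penalty forces are equal, opposite and proportional to
           overlap", {
  p <- mech_params()
  r <- p$node_radius
  c1 <- make_cell(p, head = c(0, 0))
  c2 <- make_cell(p, head = c(p$cell_length + 1.9 * r - 2 * r, 0) + c(0, 0))
  w <- make_world(list(c2, c1), p)
  ev <- detect_contacts(w)
  ev <- ev[ev$body_a <= p$n_nodes & ev$body_b <= p$n_nodes, ]
  f <- contact_forces(ev, w)
  total <- force_sum(f[[1]]) + force_sum(f[[2]])
  expect_lt(max(abs(total)), 1e-9)
  expect_equal(max(abs(f[[1]])), p$k_contact * 0.1 * r, tolerance = 1e-9)

  empty <- detect_contacts(make_world(list(
    make_cell(p, head = c(0, 0)), make_cell(p, head = c(0, 10))), p))
  f0 <- contact_forces(empty, w)
  expect_equal(max(abs(f0[[1]])), 0)
})

test_that("internal force terms each conserve momentum on arbitrary states", {
  p <- mech_params()
  for (seed in 1:5) {
    clb <- bent_cell(p, amplitude = 0.2, seed = seed)
    fj <- joint_forces(clb, p)
    fb <- bending_forces(clb, p)
    expect_lt(max(abs(force_sum(fj))), 1e-9 * max(1, max(abs(fj))))
    expect_lt(max(abs(force_sum(fb))), 1e-9 * max(1, max(abs(fb))))
  }
})

test_that("parameter validation names the offending field", {
  expect_error(mech_params(n_nodes = 2), "n_nodes")
  expect_error(mech_params(k_joint = -5), "k_joint")
  expect_error(mech_params(cell_length = 7, spacer_length = 2), "geometry")
  expect_error(adhesion_params(kappa = -1), "kappa")
  expect_error(adhesion_params(adhesion_nodes = c(1, 2)), "node 1")
  expect_error(adhesion_params(d_break = 0), "d_break")
})
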