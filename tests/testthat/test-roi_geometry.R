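test_that("TZ is the prostate minus the PZ", {
  d <- c(20L, 20L, 6L); sp <- c(1, 1, 3)
  prostate <- ball_mask(d, sp, c(10, 10, 9), 8)
  # posterior half of the prostate as PZ
  ycoord <- array(rep(rep((seq_len(d[2]) - 0.5) * sp[2], each = d[1]), d[3]), d)
  pz <- prostate & ycoord > 10

  tz <- derive_tz(prostate, pz)
  expect_equal(sum(tz), sum(prostate) - sum(pz))
  expect_true(all(tz[pz] == FALSE))

  expect_equal(sum(derive_tz(prostate, prostate)), 0)           # full subtraction
  expect_equal(derive_tz(prostate, array(FALSE, d)), prostate)  # empty PZ

  # PZ leaking outside the prostate beyond tolerance is an error
  pz_bad <- pz; pz_bad[1:5, 1:5, 1] <- TRUE
  expect_error(derive_tz(prostate, pz_bad), "outside")
  # grid mismatch
  expect_error(derive_tz(prostate, pz[, , 1:3]), "common grid")
})

test_that("peritumoral ring matches a brute-force distance scan", {
  cases <- list(
    list(d = c(15L, 15L, 15L), sp = c(1, 1, 1), ctr = c(7.5, 7.5, 7.5), r = 0.4),
    list(d = c(20L, 20L, 8L), sp = c(1.5, 1.5, 3), ctr = c(15, 15, 12), r = 4),
    list(d = c(16L, 16L, 10L), sp = c(2, 2, 2.5), ctr = c(16, 14, 12), r = 5))
  for (cs in cases) {
    gtv <- ball_mask(cs$d, cs$sp, cs$ctr, cs$r)
    expect_gt(sum(gtv), 0)
    ring <- peritumoral_ring(gtv, cs$sp, 5)
    expect_identical(ring, ring_bruteforce(gtv, cs$sp, 5))
    expect_equal(sum(ring & gtv), 0)
  }
})

test_that("single-voxel GTV ring on isotropic grid is the 5 mm ball minus seed", {
  d <- c(13L, 13L, 13L); sp <- c(1, 1, 1)
  gtv <- array(FALSE, d); gtv[7, 7, 7] <- TRUE
  ring <- peritumoral_ring(gtv, sp, 5)
  # voxel centres within 5 mm of the seed centre
  expected <- ball_mask(d, sp, c(6.5, 6.5, 6.5), 5) & !gtv
  expect_identical(ring, expected)
})

test_that("degenerate ring inputs behave", {
  d <- c(8L, 8L, 4L)
  gtv <- array(FALSE, d); gtv[4, 4, 2] <- TRUE
  expect_equal(sum(peritumoral_ring(gtv, c(1, 1, 1), 0)), 0)
  expect_error(peritumoral_ring(array(FALSE, d), c(1, 1, 1)), "empty")
})

test_that("sphere GTV ring approximates the analytic 5 mm shell volume", {
  d <- c(40L, 40L, 40L); sp <- c(1, 1, 1); r <- 6; th <- 5
  gtv <- ball_mask(d, sp, c(20, 20, 20), r)
  ring <- peritumoral_ring(gtv, sp, th)
  vol_ring <- sum(ring) * prod(sp)
  shell <- 4 / 3 * pi * ((r + th)^3 - r^3)
  expect_lt(abs(vol_ring - shell) / shell, 0.10)  # voxelization tolerance
  # inner boundary exactly excludes the GTV
  expect_equal(sum(ring & gtv), 0)
})

test_that("ring/NAT split partitions the zones", {
  d <- c(30L, 30L, 10L); sp <- c(1.5, 1.5, 3)
  prostate <- ball_mask(d, sp, c(22.5, 22.5, 15), 15)
  ycoord <- array(rep(rep((seq_len(d[2]) - 0.5) * sp[2], each = d[1]), d[3]), d)
  pz <- prostate & ycoord > 24
  tz <- derive_tz(prostate, pz)
  gtv <- ball_mask(d, sp, c(22.5, 30, 15), 4) & prostate
  ring <- peritumoral_ring(gtv, sp, 5)
  rs <- split_ring_and_nat(ring, gtv, pz, tz, prostate, sp)
  validate_roi_set(rs, prostate)

  ring_in <- ring & prostate & !gtv
  expect_equal(sum(rs$pt_pz | rs$pt_tz), sum(ring_in))          # union identity
  # partition identities per zone
  expect_equal(sum(rs$nat_pz) + sum(rs$pt_pz) + sum(gtv & pz), sum(pz))
  expect_equal(sum(rs$nat_tz) + sum(rs$pt_tz) + sum(gtv & tz), sum(tz))
})

test_that("a GTV with ring wholly inside PZ leaves PT-TZ empty", {
  d <- c(40L, 40L, 12L); sp <- c(1, 1, 2)
  prostate <- array(TRUE, d)
  ycoord <- array(rep(rep((seq_len(d[2]) - 0.5) * sp[2], each = d[1]), d[3]), d)
  pz <- ycoord > 10            # generous posterior zone
  tz <- derive_tz(prostate, pz)
  gtv <- ball_mask(d, sp, c(20, 30, 12), 3)
  ring <- peritumoral_ring(gtv, sp, 5)
  rs <- split_ring_and_nat(ring, gtv, pz, tz, prostate, sp)
  expect_equal(sum(rs$pt_tz), 0)
  expect_gt(sum(rs$pt_pz), 0)
})

test_that("multifocal merge is a union without double counting", {
  d <- c(20L, 20L, 8L); sp <- c(1, 1, 1)
  a <- ball_mask(d, sp, c(6, 6, 4), 3)
  b <- ball_mask(d, sp, c(14, 14, 4), 3)    # disjoint
  c2 <- ball_mask(d, sp, c(8, 6, 4), 3)     # overlaps a
  expect_identical(merge_multifocal(list(a)), a)
  expect_equal(sum(merge_multifocal(list(a, b))), sum(a) + sum(b))
  expect_lt(sum(merge_multifocal(list(a, c2))), sum(a) + sum(c2))
})

test_that("ROI derivation is translation-equivariant", {
  d <- c(24L, 24L, 10L); sp <- c(1.5, 1.5, 3)
  shift <- c(2L, -1L, 1L)
  mk <- function(off) {
    ctr <- c(14, 14, 14) + off * sp
    prostate <- ball_mask(d, sp, ctr, 10)
    pz <- prostate & ball_mask(d, sp, ctr + c(0, 5, 0), 8)
    gtv <- ball_mask(d, sp, ctr + c(0, 3, 0), 3)
    derive_rois(prostate, pz, gtv, sp, thickness_mm = 5)
  }
  r0 <- mk(c(0, 0, 0)); r1 <- mk(shift)
  shift_arr <- function(m) {
    out <- array(FALSE, d)
    src <- list(seq_len(d[1]) - shift[1], seq_len(d[2]) - shift[2],
                seq_len(d[3]) - shift[3])
    ok <- lapply(seq_len(3), function(i) src[[i]] >= 1 & src[[i]] <= d[i])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      m[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  for (nm in c("gtv", "pt_pz", "pt_tz", "nat_pz", "nat_tz"))
    expect_identical(r1[[nm]], shift_arr(r0[[nm]]), label = nm)
})
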