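# Superposition, residue mapping, per-residue RMSD, rASA and regions.

rot_z90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))

test_that("Kabsch superposition is exact on rigid copies", {
  set.seed(2)
  pts <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(pts, pts)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  moved <- pts %*% t(rot_z90) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(pts, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(pts[1:2, ], moved[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("Kabsch RMSD matches brute-force numeric minimization", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mov <- pts
  mov[4, ] <- mov[4, ] + c(0.7, -0.3, 0.4)   # one displaced point
  mov <- mov %*% t(rot_z90) + matrix(c(5, -1, 2), 4, 3, byrow = TRUE)
  fit <- kabsch_superpose(pts, mov)
  expect_equal(fit$rmsd, kabsch_brute_oracle(pts, mov), tolerance = 1e-6)
})

test_that("RMSD is invariant to rigid transforms of either input", {
  set.seed(8)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- kabsch_superpose(a, b)$rmsd
  a2 <- a %*% t(rot_z90) + matrix(c(3, 1, -2), 8, 3, byrow = TRUE)
  b2 <- b %*% t(rot_z90) + matrix(c(-4, 2, 9), 8, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(a2, b)$rmsd, base, tolerance = 1e-9)
  expect_equal(kabsch_superpose(a, b2)$rmsd, base, tolerance = 1e-9)
})

test_that("chain mapping recovers identity, truncations and label swaps", {
  st <- toy2(n = 12, seed = 4)
  cm <- chain_map(st, st)
  expect_equal(nrow(cm$residues), 24)
  expect_equal(cm$n_unmapped_ref, 0)
  expect_equal(cm$residues$ref_resno, cm$residues$pred_resno)

  # prediction missing 5 N-terminal residues of chain A
  trunc <- st
  trunc$atoms <- trunc$atoms[!(trunc$atoms$chain == "A" &
                                 trunc$atoms$resno <= 5), ]
  cm2 <- chain_map(st, trunc)
  expect_equal(cm2$n_unmapped_ref, 5)
  expect_equal(cm2$n_unmapped_pred, 0)
  # 7 of chain A's 12 residues map, in order (the gap location is arbitrary
  # on a homopolymer sequence)
  a_rows <- cm2$residues[cm2$residues$ref_chain == "A", ]
  expect_equal(nrow(a_rows), 7)
  expect_false(is.unsorted(a_rows$ref_resno))
  expect_false(is.unsorted(a_rows$pred_resno))

  # swapped chain labels recovered; verified against exhaustive pairing
  sw <- st
  sw$atoms$chain <- ifelse(sw$atoms$chain == "A", "B", "A")
  cm3 <- chain_map(st, sw)
  got <- cm3$chains[order(cm3$chains$ref_chain), ]
  # exhaustive 2-chain enumeration: identity of A->B pairing beats A->A
  # (both chains are poly-ALA here, so both pairings align; the map must
  # still be a bijection covering both chains)
  expect_setequal(got$ref_chain, c("A", "B"))
  expect_setequal(got$pred_chain, c("A", "B"))
  expect_equal(nrow(cm3$residues), 24)
})

test_that("sequence-distinct chain swap is recovered by identity score", {
  # two chains with different sequences: swap must be detected
  df <- data.frame(chain = rep(c("A", "B"), each = 4),
                   resno = rep(1:4, 2), elety = "CA",
                   x = rep(3.8 * (1:4), 2),
                   y = rep(c(0, 6), each = 4), z = 0.1 * (1:8))
  st <- manual_structure(df)
  st$atoms$resid <- rep(c("GLY", "TRP", "LYS", "GLU",
                          "PHE", "PHE", "SER", "SER"), 1)
  sw <- st
  sw$atoms$chain <- ifelse(sw$atoms$chain == "A", "B", "A")
  cm <- chain_map(st, sw)
  expect_equal(cm$chains$pred_chain[cm$chains$ref_chain == "A"], "B")
  expect_equal(cm$chains$pred_chain[cm$chains$ref_chain == "B"], "A")
  # exhaustive enumeration oracle on the 2-chain case
  seqs <- list(A = "GWKE", B = "FFSS")
  ident <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  straight <- ident(seqs$A, seqs$B) + ident(seqs$B, seqs$A)
  crossed <- ident(seqs$A, seqs$A) + ident(seqs$B, seqs$B)
  expect_gt(crossed, straight)
})

test_that("per-residue RMSD isolates a locally shifted residue", {
  st <- toy2(n = 100, seed = 6, noise = 0.05)   # 200 residues total
  pred <- st
  sel <- pred$atoms$chain == "A" & pred$atoms$resno == 50
  pred$atoms$x[sel] <- pred$atoms$x[sel] + 2
  rep <- per_residue_rmsd(st, pred)
  pr <- rep$per_residue
  shifted <- pr$rmsd[pr$chain == "A" & pr$resno == 50]
  expect_equal(shifted, 2, tolerance = 0.1)
  others <- pr$rmsd[!(pr$chain == "A" & pr$resno == 50)]
  expect_lt(max(others), 0.1)

  # identity comparison: all zeros
  rep0 <- per_residue_rmsd(st, st)
  expect_lt(max(rep0$per_residue$rmsd), 1e-10)
  expect_equal(rep0$global_rmsd, 0, tolerance = 1e-10)
})

test_that("global RMSD equals Kabsch on the pooled mapped backbone atoms", {
  st <- toy2(n = 15, seed = 9)
  pred <- perturb_structure(st, "flexible", amplitude = 0.5, seed = 2)
  rep <- per_residue_rmsd(st, pred)
  bb <- c("N", "CA", "C", "O")
  ra <- st$atoms[st$atoms$elety %in% bb, ]
  pa <- pred$atoms[pred$atoms$elety %in% bb, ]
  key <- function(a) paste(a$chain, a$resno, a$elety)
  m <- match(key(ra), key(pa))
  fit <- kabsch_superpose(as.matrix(ra[, c("x", "y", "z")]),
                          as.matrix(pa[m, c("x", "y", "z")]))
  expect_equal(rep$global_rmsd, fit$rmsd, tolerance = 1e-9)
})

test_that("exposed-residue ASA matches analytic areas and converges", {
  # a single isolated atom: accessible area is exactly the analytic
  # sphere area 4*pi*(r_vdw + probe)^2
  df1 <- data.frame(chain = c("A", "B"), resno = 1,
                    elety = c("CA", "CA"), x = c(0, 100), y = 0, z = 0)
  st1 <- manual_structure(df1)
  r1 <- shrake_rupley_rasa(st1, chains = "A")
  expect_equal(r1$asa[1], 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)

  # a fully exposed isolated residue exceeds the in-chain (tripeptide)
  # theoretical maximum: no flanking residues occlude its backbone
  df <- data.frame(chain = c("A", "A", "A", "A", "A", "B"),
                   resno = c(1, 1, 1, 1, 1, 1),
                   elety = c("N", "CA", "C", "O", "CB", "CA"),
                   x = c(-1.46, 0, 1.25, 1.6, -0.1, 50),
                   y = c(0.5, 0, 0.6, 1.75, -1.05, 0),
                   z = c(0.3, 0, -0.3, -0.35, 1.05, 0))
  st <- manual_structure(df)
  r <- shrake_rupley_rasa(st, chains = "A")
  expect_gt(r$rasa[1], 1)
  expect_lt(r$rasa[1], 2)
  # frozen against an independent sphere-point implementation of the same
  # atom set (probe 1.4 A, identical radii): 209.939 A^2
  expect_equal(r$asa[1], 209.939, tolerance = 1e-4)
  # doubling the sphere points moves the estimate by < 2%
  r2 <- shrake_rupley_rasa(st, chains = "A", n_points = 1920)
  expect_lt(abs(r2$rasa[1] - r$rasa[1]) / r$rasa[1], 0.02)
})

test_that("a caged residue is buried and burial is monotone", {
  core <- data.frame(chain = "A", resno = 1,
                     elety = c("N", "CA", "C", "O", "CB"),
                     x = c(-1.46, 0, 1.25, 1.6, -0.1),
                     y = c(0.5, 0, 0.6, 1.75, -1.05),
                     z = c(0.3, 0, -0.3, -0.35, 1.05))
  # dense cage of atoms on a sphere of radius 5.5
  sph <- 5.5 * plddg:::.sphere_points(300)
  cage <- data.frame(chain = "B", resno = seq_len(300), elety = "CA",
                     x = sph[, 1] + 0.2, y = sph[, 2], z = sph[, 3] + 0.5)
  far <- data.frame(chain = "B", resno = 999, elety = "CA",
                    x = 500, y = 0, z = 0)
  st_free <- manual_structure(rbind(core, far))
  st_caged <- manual_structure(rbind(core, cage))
  free <- shrake_rupley_rasa(st_free, chains = "A")$rasa[1]
  caged <- shrake_rupley_rasa(st_caged, chains = c("A", "B"))
  caged_a <- caged$rasa[caged$chain == "A"]
  expect_lt(caged_a, 0.01)
  expect_lt(caged_a, free)   # monotone burial

  # half cage buries less than full cage
  half <- manual_structure(rbind(core, cage[1:150, ]))
  half_a <- shrake_rupley_rasa(half, chains = c("A", "B"))
  expect_gte(half_a$rasa[half_a$chain == "A"][1], caged_a)
})

test_that("region rules reproduce the five-class table at the 25% cutoff", {
  expect_equal(classify_region_label(0.40, 0.10), "core")
  expect_equal(classify_region_label(0.10, 0.05), "support")
  expect_equal(classify_region_label(0.50, 0.50), "surface")
  expect_equal(classify_region_label(0.10, 0.10), "interior")
  expect_equal(classify_region_label(0.60, 0.40), "rim")
  # boundary: cutoff is strict "< 25%"
  expect_equal(classify_region_label(0.25, 0.25), "surface")
  expect_equal(classify_region_label(0.24, 0.24), "interior")
})

test_that("region labels partition partner residues and are partner-symmetric", {
  st <- toy2(n = 8, seed = 10)
  reg <- classify_regions(st)
  n_partner <- nrow(unique(st$atoms[st$atoms$chain %in% c("A", "B"),
                                    c("chain", "resno")]))
  expect_equal(nrow(reg), n_partner)
  expect_true(all(reg$region %in% c("interior", "surface", "support",
                                    "rim", "core")))
  expect_false(any(is.na(reg$region)))

  # swapping partner order leaves labels unchanged
  st2 <- st
  st2$partner_split <- list(p1 = "B", p2 = "A")
  reg2 <- classify_regions(st2)
  m <- match(paste(reg$chain, reg$resno), paste(reg2$chain, reg2$resno))
  expect_equal(reg$region, reg2$region[m])
})

test_that("evaluation summary aggregates reports and thresholds", {
  st <- toy2(n = 10, seed = 12)
  st$confidence <- new_confidence_scores(0.9, 0.9)
  pred <- perturb_structure(st, "rigid", seed = 3)
  r1 <- per_residue_rmsd(st, pred)
  r1$global_rmsd <- 1.0
  s1 <- evaluation_summary(list(r1))
  expect_equal(s1$mean_rmsd, 1.0)
  expect_equal(s1$mean_iptm, 0.9)
  expect_equal(s1$frac_iptm_high, 1.0)

  r2 <- r1; r2$global_rmsd <- 3.0; r2$complex_id <- "B"
  s2 <- evaluation_summary(list(r1, r2))
  expect_equal(s2$mean_rmsd, 2.0)
  expect_equal(s2$median_rmsd, 2.0)
  expect_equal(s2$ranking_rmsd$complex_id[1], "B")
})
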