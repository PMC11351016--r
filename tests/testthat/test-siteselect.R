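# Atom subset selection and the modified distance matrix.

test_that("mutation strings parse per the SKEMPI convention", {
  mu <- parse_mutation("EA38G")
  expect_equal(mu$wt, "E"); expect_equal(mu$chain, "A")
  expect_equal(mu$resno, 38L); expect_equal(mu$mut, "G")
  mu2 <- parse_mutation("YC100aF")
  expect_equal(mu2$icode, "a"); expect_equal(mu2$resno, 100L)
  expect_error(parse_mutation("AA5A"), "identical")
  expect_error(parse_mutation("banana"), "cannot parse")
})

test_that("mutation site atoms honor element groups and the wt check", {
  st <- toy2(n = 6)
  mu <- parse_mutation("AA3G")   # alanine 3 of chain A
  site <- mutation_site_atoms(st, mu)
  expect_equal(nrow(site$atoms), 5)   # N, CA, C, O, CB (all heavy)
  siteN <- mutation_site_atoms(st, mu, elements = "N")
  expect_equal(nrow(siteN$atoms), 1)
  expect_equal(siteN$atoms$elety, "N")
  # recorded wild type must match the residue actually present
  expect_error(mutation_site_atoms(st, parse_mutation("GA3A")), "mismatch")
  expect_error(mutation_site_atoms(st, parse_mutation("AA99G")), "not found")
})

test_that("neighborhood selection applies the distance threshold", {
  df <- data.frame(
    chain = c(rep("A", 2), "B", "B"),
    resno = c(1, 1, 1, 2),
    elety = c("CA", "CB", "CA", "CA"),
    x = c(0, 1, 3, 12), y = 0, z = 0)
  st <- manual_structure(df)
  mu <- parse_mutation("AA1G")
  nb <- neighborhood_atoms(st, mu, r = 10)
  expect_equal(nrow(nb$atoms), 1)       # 3 A atom in, 12 A atom out
  expect_equal(nb$atoms$x, 3)
  expect_error(neighborhood_atoms(st, mu, r = -1), "positive")
  # degenerate: empty surroundings is valid
  nb0 <- neighborhood_atoms(st, mu, r = 0.5)
  expect_equal(nrow(nb0$atoms), 0)
})

test_that("neighborhood membership equals a brute-force all-pairs scan", {
  st <- toy2(n = 8, seed = 3)
  mu <- parse_mutation("AB4G")
  r <- 6
  nb <- neighborhood_atoms(st, mu, r = r)
  a <- st$atoms
  in_site <- a$chain == "B" & a$resno == 4
  site_xyz <- as.matrix(a[in_site, c("x", "y", "z")])
  keep <- logical(nrow(a))
  for (i in which(!in_site)) {
    if (!a$element[i] %in% c("C", "N", "O")) next
    dmin <- min(sqrt(colSums((t(site_xyz) - unlist(a[i, c("x", "y", "z")]))^2)))
    keep[i] <- dmin <= r
  }
  got <- paste(nb$atoms$chain, nb$atoms$resno, nb$atoms$elety)
  want <- paste(a$chain[keep], a$resno[keep], a$elety[keep])
  expect_setequal(got, want)
})

test_that("binding-site selection matches a brute-force cross-chain scan", {
  st <- toy2(n = 8, seed = 5)
  r <- 6
  for (side in c("p1", "p2")) {
    bs <- binding_site_atoms(st, side, r = r)
    a <- st$atoms
    own <- if (side == "p1") "A" else "B"
    other <- setdiff(c("A", "B"), own)
    oxyz <- as.matrix(a[a$chain == other, c("x", "y", "z")])
    keep <- logical(nrow(a))
    for (i in which(a$chain == own & a$element %in% c("C", "N", "O"))) {
      dmin <- min(sqrt(colSums((t(oxyz) - unlist(a[i, c("x", "y", "z")]))^2)))
      keep[i] <- dmin <= r
    }
    expect_setequal(paste(bs$atoms$resno, bs$atoms$elety),
                    paste(a$resno[keep], a$elety[keep]))
  }
})

test_that("far-apart chains give empty binding sites; element filter is monotone", {
  st <- toy2(n = 5)
  far <- st
  far$atoms$y[far$atoms$chain == "B"] <- far$atoms$y[far$atoms$chain == "B"] + 40
  expect_equal(nrow(binding_site_atoms(far, "p1", r = 10)$atoms), 0)
  expect_equal(nrow(binding_site_atoms(far, "p2", r = 10)$atoms), 0)

  allel <- binding_site_atoms(st, "p1", r = 10, elements = c("C", "N", "O"))
  onlyO <- binding_site_atoms(st, "p1", r = 10, elements = "O")
  keyO <- paste(onlyO$atoms$resno, onlyO$atoms$elety)
  keyAll <- paste(allel$atoms$resno, allel$atoms$elety)
  expect_true(all(keyO %in% keyAll))
})

test_that("subset selections are nested in the radius", {
  st <- toy2(n = 8, seed = 11)
  mu <- parse_mutation("AA4G")
  for (rr in list(c(3, 6), c(6, 10))) {
    n1 <- neighborhood_atoms(st, mu, r = rr[1])
    n2 <- neighborhood_atoms(st, mu, r = rr[2])
    k1 <- paste(n1$atoms$chain, n1$atoms$resno, n1$atoms$elety)
    k2 <- paste(n2$atoms$chain, n2$atoms$resno, n2$atoms$elety)
    expect_true(all(k1 %in% k2))
    b1 <- binding_site_atoms(st, "p1", r = rr[1])
    b2 <- binding_site_atoms(st, "p1", r = rr[2])
    expect_true(all(paste(b1$atoms$resno, b1$atoms$elety) %in%
                      paste(b2$atoms$resno, b2$atoms$elety)))
  }
})

test_that("D_mod excludes same-subset pairs and equals Euclidean across", {
  dfa <- data.frame(chain = "A", resno = 1:2, elety = "CA",
                    x = c(0, 2), y = 0, z = 0)
  dfb <- data.frame(chain = "B", resno = 1:2, elety = "CA",
                    x = c(3, 7), y = c(4, 0), z = 0)
  st <- manual_structure(rbind(dfa, dfb))
  sa <- binding_site_atoms(st, "p1", r = 100)
  sb <- binding_site_atoms(st, "p2", r = 100)
  dm <- dmod_matrix(sa, sb)
  expect_equal(dim(dm$values), c(4, 4))
  # same-subset entries (and diagonal) excluded
  expect_true(all(!is.finite(dm$values[1:2, 1:2])))
  expect_true(all(!is.finite(dm$values[3:4, 3:4])))
  # cross entries are Euclidean: atom (0,0,0) to (3,4,0) is the 3-4-5 triangle
  expect_equal(dm$values[1, 3], 5.0)
  expect_true(isSymmetric(dm$values))
})

test_that("D_mod on a 4+4 fixture equals a direct double loop", {
  st <- toy2(n = 4, seed = 2)
  sa <- binding_site_atoms(st, "p1", r = 100)
  sb <- binding_site_atoms(st, "p2", r = 100)
  dm <- dmod_matrix(sa, sb)
  pa <- as.matrix(sa$atoms[, c("x", "y", "z")])
  pb <- as.matrix(sb$atoms[, c("x", "y", "z")])
  pts <- rbind(pa, pb)
  grp <- rep(1:2, c(nrow(pa), nrow(pb)))
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
    if (grp[i] == grp[j]) {
      expect_false(is.finite(dm$values[i, j]))
    } else {
      expect_equal(dm$values[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("element filtering commutes with distance filtering", {
  st <- toy2(n = 8, seed = 13)
  mu <- parse_mutation("AA4G")
  # filter elements first (via elements arg) vs filter afterwards
  nbC <- neighborhood_atoms(st, mu, r = 7, elements = "C")
  nbAll <- neighborhood_atoms(st, mu, r = 7, elements = c("C", "N", "O"))
  post <- nbAll$atoms[nbAll$atoms$element == "C", ]
  expect_setequal(paste(nbC$atoms$chain, nbC$atoms$resno, nbC$atoms$elety),
                  paste(post$chain, post$resno, post$elety))
})
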