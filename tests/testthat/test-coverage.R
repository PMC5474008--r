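frag <- function(strand, s1, e1, s2 = NA, e2 = NA, clip = NA, clip_pos = NA) {
  data.frame(qname = "q", transcript = "t", strand = strand, s1 = s1, e1 = e1,
             s2 = s2, e2 = e2, softclip3 = clip, clip_pos = clip_pos,
             stringsAsFactors = FALSE)
}

test_that("single reads and origin-wrapping reads increment depth correctly", {
  g <- toy_genome(len = 200)
  prof <- compute_coverage(frag("H", 1, 50), g)
  expect_equal(prof$depth_H[1:50], rep(1L, 50))
  expect_equal(sum(prof$depth_H), 50)
  expect_equal(sum(prof$depth_L), 0)
  ## wrap: read covering 191..200 and 1..40 stored as 191..240
  prof <- compute_coverage(frag("L", 191, 240), g)
  expect_equal(sum(prof$depth_L), 50)
  expect_equal(prof$depth_L[c(191:200, 1:40)], rep(1L, 50))
  expect_equal(prof$depth_L[41], 0L)
})

test_that("total incremented bases equal the summed aligned lengths", {
  set.seed(3)
  g <- toy_genome(len = 500)
  n <- 200
  s1 <- sample.int(500, n, replace = TRUE)
  fr <- data.frame(qname = paste0("q", 1:n), transcript = "t",
                   strand = sample(c("H", "L"), n, replace = TRUE),
                   s1 = s1, e1 = s1 + 49L,
                   s2 = s1 + 150L, e2 = s1 + 199L,
                   softclip3 = NA, clip_pos = NA, stringsAsFactors = FALSE)
  prof <- compute_coverage(fr, g)
  expect_equal(sum(prof$depth_H) + sum(prof$depth_L), n * 100)
})

test_that("log normalization is base-invariant, monotone and bounded", {
  g <- toy_genome(len = 100)
  fr <- do.call(rbind, lapply(1:9, function(i) frag("H", 1, 10)))
  prof <- compute_coverage(fr, g)
  prof$depth_H[20] <- 1L  # depth 1 with max 9
  norm <- suppressWarnings(normalize_log(prof))  # L strand is empty here
  expect_equal(norm$H$values[20], log(2) / log(10), tolerance = 1e-12)
  expect_equal(norm$H$values[1], 1)
  expect_true(all(norm$H$values >= 0 & norm$H$values <= 1))
  ## order isomorphism with raw depth
  set.seed(5)
  prof$depth_H <- sample.int(50, 100, replace = TRUE)
  v <- suppressWarnings(normalize_log(prof))$H$values
  expect_equal(order(v), order(prof$depth_H))
  ## all-zero strand warns and yields zeros
  prof$depth_H <- integer(100); prof$depth_L <- integer(100)
  ws <- testthat::capture_warnings(nz <- normalize_log(prof))
  expect_match(ws, "all-zero", all = TRUE)
  expect_true(all(nz$H$values == 0))
})

test_that("zero-coverage segments merge across the origin", {
  g <- toy_genome(len = 200)
  prof <- compute_coverage(frag("H", 1, 200), g)  # fully covered
  expect_equal(nrow(zero_coverage_segments(prof)), 0)
  ## zeros at 100..150 only
  prof$depth_H[] <- 1L; prof$depth_H[100:150] <- 0L
  segs <- zero_coverage_segments(prof, min_len = 20)
  expect_equal(segs, data.frame(start = 100L, end = 150L, length = 51L))
  ## zeros wrapping the origin: 195..200 and 1..10
  prof$depth_H[] <- 1L
  prof$depth_H[c(195:200, 1:10)] <- 0L
  segs <- zero_coverage_segments(prof)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 195L)
  expect_equal(segs$end, 10L)
  expect_equal(segs$length, 16L)
  ## complement partition: zero segments + covered runs tile the circle
  expect_equal(segs$length + sum(prof$depth_H > 0), 200)
})

test_that("a coverage step produces one fall breakpoint at the step", {
  g <- toy_genome(len = 1000)
  prof <- compute_coverage(frag("H", 1, 1000), g)
  prof$depth_H <- c(rep(100L, 499), rep(10L, 501))
  bp <- find_breakpoints(prof, window = 50, min_ratio = 5)
  ## on a circle a single step creates two discontinuities: the fall at the
  ## step and the rise where the profile wraps past the origin
  fall <- bp[bp$direction == "fall", ]
  expect_equal(nrow(fall), 1)
  expect_equal(fall$position, 500)
  expect_equal(fall$drop_ratio, 10, tolerance = 0.01)
  rise <- bp[bp$direction == "rise", ]
  expect_true(all(rise$position <= 26 | rise$position >= 975))
  ## flat profile: none
  prof$depth_H <- rep(30L, 1000)
  expect_equal(nrow(find_breakpoints(prof)), 0)
})

test_that("SAM files written by the simulator reload to identical coverage", {
  b <- arrangement_a()
  sim <- simulate_reads(b$program, b$features, b$genome, depth = 2,
                        rrna_multiplier = 2, readthrough_fraction = 0,
                        seed = 9)
  prof_mem <- compute_coverage(sim$fragments, b$genome)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$fragments, b$genome, sam)
  prof_sam <- compute_coverage(sam, b$genome, protocol = "unstranded")
  ## unstranded file reading assigns by alignment strand; mate2 of an H
  ## fragment maps reverse, so compare combined depth
  expect_equal(prof_sam$depth_H + prof_sam$depth_L,
               prof_mem$depth_H + prof_mem$depth_L)
})

test_that("breakpoint appears in the IGR between units with an abundance gap", {
  b <- arrangement_a()
  sim <- simulate_reads(b$program, b$features, b$genome, depth = 30,
                        rrna_multiplier = 20, readthrough_fraction = 0,
                        seed = 21)
  prof <- compute_coverage(sim$fragments, b$genome)
  bp <- find_breakpoints(prof, window = 50, min_ratio = 5)
  coi_end <- b$features$end[b$features$name == "COI"]
  s12_start <- b$features$start[b$features$name == "12S"]
  in_igr <- bp$strand == "H" & bp$position > coi_end - 25 &
    bp$position < s12_start + 25
  expect_true(any(in_igr))
})
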