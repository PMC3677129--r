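test_that("the pivot threshold F = P*N/32 is exact rational arithmetic", {
  expect_equal(threshold(2000, 1), 62.5)
  expect_equal(threshold(576, 1), 18)
  for (N in c(1, 31, 32, 33, 577, 12345)) {
    expect_equal(threshold(N, 32), N)   # P = 32: AER always
    expect_equal(threshold(N, 0), 0)    # P = 0: bit-packing for any S > 0
  }
  expect_error(pivot_config(-0.5))
  expect_error(pivot_config(33))
})

test_that("step spike sets validate their indices", {
  expect_error(step_spikes(c(0, 0), 4), "duplicate")
  expect_error(step_spikes(4, 4), "\\[0, N\\)")
  expect_error(step_spikes(-1, 4), "\\[0, N\\)")
  sp <- step_spikes(c(3, 1), 4)
  expect_identical(sp$fired_local, c(1L, 3L))
  expect_equal(sp$S, 2)
})

test_that("AER packets carry the firing count and sorted indices", {
  empty <- encode_aer(step_spikes(integer(0), 100))
  expect_equal(empty$header, 0L)
  expect_length(empty$payload, 0)
  expect_equal(packet_payload_words(empty), 0)

  sp <- step_spikes(sample.int(2000, 72) - 1L, 2000)
  pk <- encode_aer(sp)
  expect_equal(pk$header, 72L)
  expect_equal(pk$scheme, "AER")
  expect_equal(packet_payload_words(pk), 72)
  expect_identical(as.integer(pk$payload), sp$fired_local)
})

test_that("bit-packed payload size depends only on N, never on activity", {
  # worked-example sizes
  expect_equal(packet_payload_words(encode_bitpacked(step_spikes(0:9, 576))),
               18)
  expect_equal(packet_payload_words(encode_bitpacked(step_spikes(0:71, 2000))),
               63)
  set.seed(1)
  for (N in c(1, 31, 32, 33, 64, 100, 576)) {
    sizes <- vapply(c(0, 1, N %/% 2, N), function(S) {
      packet_payload_words(encode_bitpacked(random_step(N, S)))
    }, 0)
    expect_true(all(sizes == ceiling(N / 32)))
  }
})

test_that("bit positions are LSB-first within ascending words", {
  pk <- encode_bitpacked(step_spikes(c(0L, 31L), 32))
  expect_equal(pk$payload, 2^0 + 2^31)  # 0x80000001
  expect_equal(pk$header, -1L)
  pk2 <- encode_bitpacked(step_spikes(c(1L, 32L, 63L), 64))
  expect_equal(pk2$payload, c(2, 2^0 + 2^31))
})

test_that("all codecs round-trip randomized firing sets exactly", {
  set.seed(7)
  for (i in 1:40) {
    N <- sample(1:300, 1)
    S <- sample(0:N, 1)
    sp <- random_step(N, S)
    expect_identical(decode(encode_aer(sp), N)$fired_local, sp$fired_local)
    expect_identical(decode(encode_bitpacked(sp), N)$fired_local,
                     sp$fired_local)
    P <- sample(c(0, 1, 2, 3, 10, 20, 32), 1)
    expect_identical(decode(encode_hybrid(sp, P), N)$fired_local,
                     sp$fired_local)
  }
})

test_that("hybrid scheme choice follows the worked example at N = 2000, P = 1", {
  s50 <- encode_hybrid(step_spikes(0:49, 2000), 1)   # S = 50 <= 62.5
  expect_equal(s50$scheme, "AER")
  expect_equal(packet_payload_words(s50), 50)
  s72 <- encode_hybrid(step_spikes(0:71, 2000), 1)   # S = 72 > 62.5
  expect_equal(s72$scheme, "BITPACKED")
  expect_equal(packet_payload_words(s72), 63)
})

test_that("scheme choice matches the literal S <= F rule exhaustively (N <= 128)", {
  for (P in c(0L, 1L, 32L)) {
    for (N in 1:128) {
      schemes <- vapply(0:N, function(S) {
        encode_hybrid(step_spikes(seq_len(S) - 1L, N), P)$scheme
      }, "")
      # oracle: S <= P*N/32 evaluated in exact integer arithmetic
      oracle <- ifelse((0:N) * 32L <= P * N, "AER", "BITPACKED")
      expect_identical(schemes, oracle)
    }
  }
})

test_that("P = 1 hybrid packets are minimal and bounded (N <= 512)", {
  bound_ok <- TRUE
  minimal_ok <- TRUE
  for (N in 1:512) {
    cap <- ceiling(N / 32)
    bp_words <- packet_payload_words(encode_bitpacked(step_spikes(integer(0),
                                                                  N)))
    for (S in 0:N) {
      sp <- step_spikes(seq_len(S) - 1L, N)
      h <- packet_payload_words(encode_hybrid(sp, 1))
      a <- packet_payload_words(encode_aer(sp))
      if (h != min(a, bp_words)) minimal_ok <- FALSE
      if (h > cap) bound_ok <- FALSE
    }
  }
  expect_true(minimal_ok)   # never worse than the better pure codec
  expect_true(bound_ok)     # deterministic upper bound ceiling(N/32)
})

test_that("the crossing fraction is ceiling(N/32)/N of the population", {
  for (N in c(576, 2000, 64, 33)) {
    w <- ceiling(N / 32)
    sizes <- vapply(0:N, function(S) {
      packet_payload_words(encode_hybrid(step_spikes(seq_len(S) - 1L, N), 1))
    }, 0)
    first_bp <- which(sizes < 0:N)[1] - 1L  # first S where hybrid beats AER
    expect_equal(first_bp, w + 1L)          # strict win starts one past w
    expect_equal(sizes[w + 1L], w)          # payload is exactly w at S = w
  }
  expect_equal(100 * ceiling(576 / 32) / 576, 3.125)
})

test_that("malformed packets are rejected with distinct errors", {
  ok <- encode_aer(step_spikes(c(0L, 5L), 32))
  bad_len <- ok; bad_len$payload <- bad_len$payload[1]
  expect_error(decode(bad_len, 32), "header")
  bad_idx <- ok; bad_idx$payload <- c(0, 40)
  expect_error(decode(bad_idx, 32), "index >= N")

  bp <- encode_bitpacked(step_spikes(0L, 64))
  short <- bp; short$payload <- short$payload[1]
  expect_error(decode(short, 64), "expected 2 payload words")
  stray <- encode_bitpacked(step_spikes(0L, 32))
  stray$payload <- 2^33 %% 2^32 + 2^31  # bit 31 set, N = 20
  expect_error(decode(stray, 20), "set bit")

  # negative header with an all-zero word decodes to the empty set
  empty <- structure(list(header = -1L, payload = 0, N = 32L,
                          scheme = "BITPACKED"), class = "spike_packet")
  expect_equal(decode(empty, 32)$S, 0)
})

test_that("the binary wire format is little-endian header + payload words", {
  path <- tempfile(fileext = ".bin")
  pk_aer <- encode_aer(step_spikes(c(5L, 7L), 40))
  pk_bp <- encode_bitpacked(step_spikes(c(0L, 31L), 32))
  write_packets(list(pk_aer, pk_bp), path)
  raw <- readBin(path, "raw", n = 1000)
  expect_identical(
    raw[1:12],
    as.raw(c(0x02, 0, 0, 0, 0x05, 0, 0, 0, 0x07, 0, 0, 0)))
  expect_identical(raw[13:16], as.raw(c(0xff, 0xff, 0xff, 0xff)))  # header -1
  expect_identical(raw[17:20], as.raw(c(0x01, 0, 0, 0x80)))        # 0x80000001
  unlink(path)
})

test_that("packet streams round-trip through the wire format", {
  set.seed(13)
  N <- 70
  packets <- lapply(1:20, function(i) {
    sp <- random_step(N, sample(0:N, 1))
    encode_hybrid(sp, sample(c(0, 1, 32), 1))
  })
  path <- tempfile(fileext = ".bin")
  write_packets(packets, path)
  back <- read_packets(path, N)
  expect_length(back, 20)
  for (i in seq_along(packets)) {
    expect_equal(back[[i]]$header, packets[[i]]$header)
    expect_equal(back[[i]]$payload, packets[[i]]$payload)
    expect_identical(decode(back[[i]], N)$fired_local,
                     decode(packets[[i]], N)$fired_local)
  }
  unlink(path)
})
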