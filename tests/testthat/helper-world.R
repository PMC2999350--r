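# Shared synthetic fixtures, built once per test run.

test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- netonco::generate_world(n = 600, seed = 101)
    cache
  }
})

# A moderately sized fixed network for calibration/recovery simulations.
test_pa_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- netonco::generate_network(2000, seed = 11)
    }
    cache
  }
})

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
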