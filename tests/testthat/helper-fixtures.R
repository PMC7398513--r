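# Shared, lazily-built fixtures. Everything is generated in code; nothing
# is read from disk except the bundled reference files.

.faw_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .faw_cache)) assign(key, builder(), envir = .faw_cache)
  get(key, envir = .faw_cache)
}

test_refs <- function() memo("refs", faw_references)

test_fixture <- function() memo("fixture", function() ecuador_fixture(test_refs()))

test_fixture_calls <- function() memo("fixture_calls", function() {
  fx <- test_fixture()
  classify_specimens(fx$specimens, test_refs(), registry = fx$panel$sequences)
})

# random DNA string helpers
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# install a base at a 1-based position of a sequence string
set_base <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

# write a character vector to a temp file, return path
tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
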