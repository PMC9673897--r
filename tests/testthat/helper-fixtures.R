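# Shared synthetic fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_bundle <- function() {
  cached("default_bundle", generate_city(city_config(seed = 42)))
}

default_result <- function() {
  cached("default_result", sdi_pipeline(default_bundle()))
}

edge_bundle <- function() {
  cached("edge_bundle", generate_edge_cases(seed = 42))
}

edge_result <- function() {
  cached("edge_result", suppressMessages(sdi_pipeline(edge_bundle())))
}

local_crs <- function() sdi_crs("local", lon0 = 30, lat0 = -10)

# Match each planted truth row to the scored unit containing the block
# centroid; returns merged data.frame (truth columns prefixed "t_").
match_truth <- function(bundle, result) {
  tr <- bundle$truth[bundle$truth$planted, , drop = FALSE]
  d <- result$records$data
  idx <- vapply(seq_len(nrow(tr)), function(k) {
    hit <- which(vapply(result$records$geometry, function(g)
      isTRUE(sdindex:::points_in_region(tr$cx[k], tr$cy[k],
                                        sdindex:::as_region(g))),
      logical(1)))
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1))
  cbind(tr, d[idx, c("BUILT_PROP", "POP_DENS", "BUILTscore", "POPscore",
                     "INDEXvalue")] |>
          stats::setNames(paste0("got_", c("BUILT_PROP", "POP_DENS",
                                           "BUILTscore", "POPscore",
                                           "INDEXvalue"))))
}
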