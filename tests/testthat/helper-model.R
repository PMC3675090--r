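# Shared fixtures. Angle-response tables are deterministic and expensive, so
# they are computed once per test session and memoized here.

.table_cache <- new.env(parent = emptyenv())

cached_table <- function(key, protocol, params,
                         policy = reorientation_policy(),
                         resolution_deg = 1) {
  if (is.null(.table_cache[[key]])) {
    .table_cache[[key]] <- angle_response_table(
      protocol, params, policy, resolution_deg = resolution_deg)
  }
  .table_cache[[key]]
}

table_normal_1hz <- function() {
  cached_table("normal_1hz", stretch_protocol(0.1, 1), model_params())
}

table_normal_02hz <- function() {
  cached_table("normal_02hz", stretch_protocol(0.1, 0.2), model_params())
}

table_static <- function() {
  cached_table("static", stretch_protocol(0, 0), model_params())
}

rho_params <- function() model_params(c = 0.1)
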