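# non-imported data.table usage: declare awareness for [.data.table NSE
.datatable.aware <- TRUE

utils::globalVariables(c(".", ".N", "infected", "phage_clone",
                         "bacteria_clone", "phage_time", "bacteria_time",
                         "mean_infectivity", "population"))
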