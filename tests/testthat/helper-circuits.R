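# Shared fixtures: two functional half-center circuits found by the package's
# own seeded self-refining scan (sample_neurons(40, seed = 11), scan seeds
# 5014 / 5021) and frozen here so tests do not pay the search cost.  Both are
# verified functional at 4.5 s and 120 s by test-population.R.

fixture_circuit_a <- function() {
  circuit_parameters(
    neuron_parameters(c(Na = 1003.7294020876288, CaT = 5.2168536367826164,
                        CaS = 10.123422179371119, A = 108.02655210718513,
                        KCa = 130.29056983068585, Kd = 118.42347929254174,
                        H = 1.449578101746738), neuron_id = "n11_32"),
    neuron_parameters(c(Na = 997.4695049226284, CaT = 3.920676161069423,
                        CaS = 3.9483096627518535, A = 115.02766085788608,
                        KCa = 96.534788385033607, Kd = 90.413417865056545,
                        H = 1.0583296222612262), neuron_id = "n11_7"),
    synapse_parameters(0.33500000000000008, 0.28750000000000003),
    circuit_id = "fixA")
}

fixture_circuit_b <- function() {
  circuit_parameters(
    neuron_parameters(c(Na = 1133.7452157400548, CaT = 3.0171355409547687,
                        CaS = 7.1731291869655252, A = 66.815457802731544,
                        KCa = 57.464557848870754, Kd = 96.657816746737808,
                        H = 0.8868524581193924), neuron_id = "n11_8"),
    neuron_parameters(c(Na = 932.93780591338873, CaT = 2.1840692446567118,
                        CaS = 2.643597942776978, A = 25.595236783847213,
                        KCa = 79.555848315358162, Kd = 105.24391382234171,
                        H = 0.47185077937319875), neuron_id = "n11_12"),
    synapse_parameters(0.20750000000000002, 0.0625),
    circuit_id = "fixB")
}

# reduced-duration grid spec for tests that only need rhythm extraction
fast_grid <- function() synaptic_grid_spec(eval_duration = 2000,
                                           validation_duration = 20000)
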