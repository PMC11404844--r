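# Aliases for non-exported functions exercised directly by unit tests.
active_force_length_deriv <- exoassist:::active_force_length_deriv
force_velocity_deriv <- exoassist:::force_velocity_deriv
force_velocity_inverse <- exoassist:::force_velocity_inverse
passive_force_length_deriv <- exoassist:::passive_force_length_deriv
tendon_force_length_deriv <- exoassist:::tendon_force_length_deriv
tendon_force_length_inverse <- exoassist:::tendon_force_length_inverse
activation_rate <- exoassist:::activation_rate
activation_rate_partials <- exoassist:::activation_rate_partials
activation_inverse <- exoassist:::activation_inverse
hill_equilibrium_solve <- exoassist:::hill_equilibrium_solve
rigid_tendon_state <- exoassist:::rigid_tendon_state
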