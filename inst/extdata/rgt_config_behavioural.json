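{"option_labels":["A","B","C","D"],"reward_pellets":[2,2,1,1],"timeout_seconds":[444,222,12,6],"penalty_prob":[0.5,0.25,0.25,0.5],"penalty_pellets":[-50,-25,-1.33333333333333,-0.666666666666667],"episode_seconds":9,"session_seconds":3600,"pellet_cap":250,"forced_exploration_seconds":600,"bin_seconds":600,"advantageous_set":["C","D"],"penalty_values":"canonical","clock":"behavioural","location_map":{"A":1,"B":2,"C":3,"D":4}}
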