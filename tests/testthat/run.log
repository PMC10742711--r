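07:36:04 subcommand: frobnicate 
07:36:04 subcommand: shannon 
07:36:04 subcommand: shannon 
07:36:04 subcommand: leibovici 
07:36:17 subcommand: frobnicate 
07:36:17 subcommand: shannon 
07:36:17 subcommand: shannon 
07:36:17 subcommand: leibovici 
07:37:30 subcommand: frobnicate 
07:37:30 subcommand: shannon 
07:37:30 subcommand: shannon 
07:37:30 subcommand: leibovici 
07:37:55 subcommand: frobnicate 
07:37:55 subcommand: shannon 
07:37:55 subcommand: shannon 
07:37:55 subcommand: leibovici 
07:38:29 subcommand: frobnicate 
07:38:29 subcommand: shannon 
07:38:29 subcommand: shannon 
07:38:29 subcommand: leibovici 
07:40:33 subcommand: frobnicate 
07:40:33 subcommand: shannon 
07:40:33 subcommand: shannon 
07:40:33 subcommand: leibovici 
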