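"experiment_id","publication","injection chemical","injection location","taxonomic class","labeling location","labeling density","labeling type"
"beckstead-e1","Beckstead-1976","HRP","coextensive_with(ENT)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"beckstead-e2","Beckstead-1976","HRP","coextensive_with(ENTl)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"beckstead-e3","Beckstead-1976","HRP","coextensive_with(ENTm)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"deacon-e1","Deacon-1983","HRP","overlaps(ENT)|overlaps(ENTadj1)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"deacon-e2","Deacon-1983","HRP","overlaps(ENT)|overlaps(ENTadj2)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"deacon-e3","Deacon-1983","HRP","overlaps(ENT)|overlaps(ENTadj3)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"swanson77-e1","Swanson-1977","HRP","coextensive_with(ENT)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"swanson81-e1","Swanson-1981","HRP","coextensive_with(ENT)","Rattus norvegicus","coextensive_with(CA1)","present-unknown","cellular"
"vangroen-e1","vanGroen-1990","PHA-L","coextensive_with(CA1)","Rattus norvegicus","coextensive_with(ENT)","present-unknown","terminals"
"vangroen-e2","vanGroen-1990","PHA-L","coextensive_with(CA1)","Rattus norvegicus","coextensive_with(ENT)","present-unknown","terminals"
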