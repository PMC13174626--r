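format-version: 1.2

[Term]
id: GO:0000001
name: molecular_function root
namespace: molecular_function

[Term]
id: GO:0000002
name: binding-like activity
namespace: molecular_function
is_a: GO:0000001 ! molecular_function root
alt_id: GO:0000099

[Term]
id: GO:0000003
name: specific binding activity
namespace: molecular_function
is_a: GO:0000002 ! binding-like activity

[Term]
id: GO:0000004
name: biological_process root
namespace: biological_process

[Term]
id: GO:0000005
name: some process
namespace: biological_process
is_a: GO:0000004 ! biological_process root

[Term]
id: GO:0000006
name: cellular_component root
namespace: cellular_component

[Term]
id: GO:0000007
name: some component
namespace: cellular_component
is_a: GO:0000006 ! cellular_component root

[Term]
id: GO:0000008
name: obsolete old activity
namespace: molecular_function
is_obsolete: true
replaced_by: GO:0000003
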