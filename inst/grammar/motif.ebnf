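(* Motif query DSL — normative grammar (EBNF).
   The language is whitespace-agnostic within statements; statements are
   separated by newlines or semicolons; comments run from '#' to end of
   line. A leading comment block of the form "# key: value" carries
   provenance metadata. *)

motif_file      = { provenance_line } , { statement_sep } ,
                  statement , { statement_sep , statement } , { statement_sep } ;

provenance_line = "#" , key , ":" , text , newline ;

statement       = edge | non_edge | node_constraint | interchangeable
                | macro_def | macro_call ;
statement_sep   = newline | ";" ;

edge            = ident , "->" , ident , [ edge_attrs ] ;
non_edge        = ident , ( "!>" | "!->" ) , ident ;
edge_attrs      = "[" , predicate , { "," , predicate } , "]" ;

node_constraint = ident , "." , ident , op , rhs ;
predicate       = ident , op , rhs ;
rhs             = value | ident , "." , ident ;   (* literal or node.attr *)

interchangeable = ident , "===" , ident ;

macro_def       = ident , "(" , [ param_list ] , ")" , "{" ,
                  { statement_sep } ,
                  { macro_stmt , statement_sep } , "}" ;
macro_stmt      = edge | non_edge | node_constraint | interchangeable
                | macro_call ;
                  (* macro bodies may reference only the macro's own
                     parameters and other (non-recursive) macros *)
param_list      = ident , { "," , ident } ;
macro_call      = ident , "(" , [ arg_list ] , ")" ;
arg_list        = ident , { "," , ident } ;

op              = "=" | "==" | "!=" | "<" | "<=" | ">" | ">="
                | "in" | "contains" ;

value           = string | number | boolean | list ;
list            = "[" , [ value , { "," , value } ] , "]" ;
string          = '"' , { character - '"' } , '"' ;
number          = [ "+" | "-" ] , digits , [ "." , digits ] ,
                  [ ( "e" | "E" ) , [ "+" | "-" ] , digits ] ;
boolean         = "true" | "false" ;
ident           = letter_or_underscore , { letter_or_digit_or_underscore } ;
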